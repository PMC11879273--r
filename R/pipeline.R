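#' Full morphometric analysis of a landmark dataset
#'
#' Runs the complete shape pipeline: symmetric-component Procrustes
#' superimposition, allometry correction on log10 centroid size, PCA,
#' truncation to the leading PCs, sex and area discriminant-vector angles,
#' sex jackknife, multi-group and pairwise jackknife classification,
#' Procrustes/Mahalanobis distance matrices, Hotelling's T2 tests,
#' dispersion and centroid-size comparisons.
#'
#' @param dat a [landmark_dataset()].
#' @param pairing a [symmetry_pairing()].
#' @param n_pcs number of leading principal components used in all
#'   multivariate comparisons (default 10).
#' @param groups declared group order (classification tie-break and table
#'   order); default: order of first appearance.
#' @param pooled_var use pooled-variance Student t tests for dispersion and
#'   centroid size (default Welch).
#' @return list of class \code{morph_analysis} with elements \code{sym}
#'   (symmetric shapes), \code{allometry}, \code{pca}, \code{scores}
#'   (n x n_pcs), \code{cum_var} (cumulative variance fractions),
#'   \code{sex_jackknife}, \code{area_jackknife}, \code{pairwise}
#'   (data.frame of pairwise success rates), \code{procrustes_dist},
#'   \code{mahalanobis_dist}, \code{hotelling} (data.frame), \code{angles}
#'   (sex vector vs area-pair vectors), \code{dispersion},
#'   \code{centroid_size_tests}, \code{n_pcs}, \code{groups}.
#' @export
morphometrics_analysis <- function(dat, pairing, n_pcs = 10L,
                                   groups = unique(dat$group),
                                   pooled_var = FALSE) {
  sym <- symmetric_component(dat, pairing)
  fit <- allometry_residuals(sym$shapes, sym$cs)
  pca <- shape_pca(fit$residuals)
  n_pcs <- min(n_pcs, ncol(pca$scores))
  scores <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  grp <- dat$group

  # sexual dimorphism: known-sex specimens only
  known <- dat$sex %in% c("F", "M")
  sex_jack <- NULL
  sex_vec <- NULL
  if (sum(known) >= 4L && length(unique(dat$sex[known])) == 2L) {
    sex_jack <- jackknife_classify(scores[known, , drop = FALSE],
                                   dat$sex[known], groups = c("F", "M"))
    sex_vec <- discriminant_vector(scores[known, , drop = FALSE],
                                   dat$sex[known], "M", "F")
  }

  # discriminant-vector angles: sex vector vs each area-pair vector
  angles <- NULL
  if (!is.null(sex_vec) && length(groups) >= 2L) {
    rows <- list()
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      av <- discriminant_vector(scores, grp, groups[i], groups[j],
                                pool = groups)
      rows[[length(rows) + 1L]] <-
        data.frame(pair = paste(groups[i], groups[j], sep = "-"),
                   angle_deg = vector_angle(sex_vec, av),
                   stringsAsFactors = FALSE)
    }
    angles <- do.call(rbind, rows)
  }

  area_jack <- jackknife_classify(scores, grp, groups = groups)
  pw <- list(); pr <- mh <- matrix(NA_real_, length(groups), length(groups),
                                   dimnames = list(groups, groups))
  ht <- list()
  means <- lapply(groups, function(g)
    colMeans(flatten_shapes(sym$shapes)[grp == g, , drop = FALSE]))
  names(means) <- groups
  for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
    gA <- groups[i]; gB <- groups[j]
    cl <- pairwise_classify(scores, grp, gA, gB)
    pw[[length(pw) + 1L]] <- data.frame(pair = paste(gA, gB, sep = "-"),
                                        success = cl$overall,
                                        stringsAsFactors = FALSE)
    pr[i, j] <- pr[j, i] <- procrustes_distance(means[[gA]], means[[gB]])
    mh[i, j] <- mh[j, i] <- mahalanobis_distance(scores, grp, gA, gB,
                                                 pool = groups)
    h <- hotelling_t2(scores, grp, gA, gB)
    ht[[length(ht) + 1L]] <- data.frame(pair = paste(gA, gB, sep = "-"),
                                        t2 = h$t2, f = h$f, df1 = h$df1,
                                        df2 = h$df2, p_value = h$p_value,
                                        stringsAsFactors = FALSE)
  }
  disp <- dispersion_stats(fit$residuals, grp, pooled_var = pooled_var)
  cs_tests <- dispersion_stats(matrix(sym$cs, ncol = 1), grp,
                               pooled_var = pooled_var)
  structure(list(sym = sym, allometry = fit, pca = pca, scores = scores,
                 cum_var = pca$cum_var,
                 sex_jackknife = sex_jack, sex_vector = sex_vec,
                 area_jackknife = area_jack,
                 pairwise = do.call(rbind, pw),
                 procrustes_dist = pr, mahalanobis_dist = mh,
                 hotelling = do.call(rbind, ht), angles = angles,
                 dispersion = disp, centroid_size_tests = cs_tests,
                 n_pcs = n_pcs, groups = groups),
            class = "morph_analysis")
}

#' @export
print.morph_analysis <- function(x, ...) {
  cat("morph_analysis on", nrow(x$scores), "specimens,", x$n_pcs, "PCs (",
      sprintf("%.1f%%", 100 * x$cum_var[x$n_pcs]), "of variance )\n")
  cat("area jackknife overall success:",
      sprintf("%.1f%%", 100 * x$area_jackknife$overall), "\n")
  if (!is.null(x$sex_jackknife))
    cat("sex jackknife success:",
        sprintf("%.1f%%", 100 * x$sex_jackknife$overall), "\n")
  invisible(x)
}

# Header comment carrying provenance for every written table.
run_header <- function(config, seed) {
  # hash the scientific configuration only, not output locations
  cfg <- config[setdiff(names(config), c("out_dir"))]
  sprintf("# norppa %s | seed=%s | config_sha=%s",
          as.character(utils::packageVersion("norppa")), seed,
          substr(digest_config(cfg), 1, 12))
}

digest_config <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  # tiny FNV-1a hash, enough to tag outputs with their configuration
  h <- 0
  for (b in as.integer(raw)) h <- (bitwXor(h, b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the population-genetics arm end to end
#'
#' Reads (or accepts) an alignment with population labels and produces the
#' per-area diversity table, pairwise Kst/dA matrices with permutation
#' p-values, the taxonomic threshold assessment, and the median-joining
#' network, writing deterministic TSV/GraphML outputs.
#'
#' @param config list with elements: \code{alignment} (a
#'   [seal_alignment()]) or \code{fasta}/\code{popmap} paths; optional
#'   \code{areas}; \code{n_perm} (default 1000); \code{seed} (mandatory);
#'   \code{epsilon} (default 0); \code{out_dir} (default: no files
#'   written).
#' @return list with \code{diversity} (per-area table), \code{diff}
#'   (Kst/p/dA matrices), \code{thresholds}, \code{network}, \code{files}.
#' @export
run_popgen <- function(config) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  aln <- config[["alignment"]]
  if (is.null(aln)) aln <- read_fasta_alignment(config[["fasta"]], config[["popmap"]])
  areas <- if (is.null(config$areas)) unique(aln$pops) else config$areas
  n_perm <- if (is.null(config$n_perm)) 1000L else config$n_perm
  epsilon <- if (is.null(config$epsilon)) 0L else config$epsilon
  div <- diversity_table(aln, areas)
  diff <- differentiation_matrix(aln, areas, n_perm = n_perm,
                                 seed = config$seed)
  thr <- assess_taxonomic_thresholds(diff$da)
  net <- build_mjn(collapse_haplotypes(aln), epsilon = epsilon)
  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- run_header(config, config$seed)
    f1 <- file.path(config$out_dir, "diversity_table.tsv")
    tab1 <- data.frame(Area = div$Area, N = div$N, h = div$h,
                       P = round(div$P, 3), Hd = round(div$Hd, 3),
                       pi = round(div$pi_printed, 3), S = div$S,
                       K = round(div$K, 1))
    write_tsv_with_header(tab1, f1, hdr)
    f2 <- file.path(config$out_dir, "differentiation_matrix.tsv")
    write_tsv_with_header(cbind(Area = rownames(diff$kst), diff$combined),
                          f2, hdr)
    f3 <- file.path(config$out_dir, "kst_pvalues.tsv")
    write_tsv_with_header(cbind(Area = rownames(diff$p), as.data.frame(diff$p)),
                          f3, hdr)
    f4 <- file.path(config$out_dir, "taxonomic_thresholds.tsv")
    write_tsv_with_header(thr, f4, hdr)
    f5 <- file.path(config$out_dir, "network.graphml")
    export_network(net, f5, "graphml")
    f6 <- file.path(config$out_dir, "network_edges.tsv")
    export_network(net, f6, "tsv")
    files <- c(f1, f2, f3, f4, f5, f6)
  }
  list(diversity = div, diff = diff, thresholds = thr, network = net,
       files = files)
}

#' Run the geometric-morphometrics arm end to end
#'
#' @param config list with elements: \code{dataset} (a
#'   [landmark_dataset()]) or \code{landmarks_csv} path; \code{pairing} (a
#'   [symmetry_pairing()]) or \code{pairing_tsv} path; \code{n_pcs}
#'   (default 10); \code{seed} (mandatory, recorded in output headers);
#'   optional \code{groups}, \code{out_dir}.
#' @return the [morphometrics_analysis()] result, plus \code{files}.
#' @export
run_morphometrics <- function(config) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  dat <- config[["dataset"]]
  if (is.null(dat)) dat <- read_landmarks_csv(config[["landmarks_csv"]])
  pairing <- config[["pairing"]]
  if (is.null(pairing)) pairing <- read_pairing(config[["pairing_tsv"]], dat$k)
  n_pcs <- if (is.null(config$n_pcs)) 10L else config$n_pcs
  groups <- if (is.null(config$groups)) unique(dat$group) else config$groups
  res <- morphometrics_analysis(dat, pairing, n_pcs = n_pcs, groups = groups)
  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- run_header(config, config$seed)
    f <- character()
    f[1] <- file.path(config$out_dir, "distance_matrices.tsv")
    k <- length(groups)
    comb <- matrix("", k, k, dimnames = list(groups, groups))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i < j) comb[i, j] <- sprintf("%.3f", res$procrustes_dist[i, j])
      if (i > j) comb[i, j] <- sprintf("%.3f", res$mahalanobis_dist[i, j])
    }
    write_tsv_with_header(cbind(Area = groups, as.data.frame(comb)), f[1], hdr)
    f[2] <- file.path(config$out_dir, "area_jackknife.tsv")
    conf <- res$area_jackknife$confusion
    tab <- data.frame(Origin = rownames(conf), conf,
                      rate = round(res$area_jackknife$rates, 2),
                      check.names = FALSE)
    write_tsv_with_header(tab, f[2], hdr)
    f[3] <- file.path(config$out_dir, "pairwise_jackknife.tsv")
    write_tsv_with_header(res$pairwise, f[3], hdr)
    f[4] <- file.path(config$out_dir, "hotelling.tsv")
    write_tsv_with_header(res$hotelling, f[4], hdr)
    if (!is.null(res$angles)) {
      f[5] <- file.path(config$out_dir, "sex_area_angles.tsv")
      write_tsv_with_header(res$angles, f[5], hdr)
    }
    f[length(f) + 1L] <- file.path(config$out_dir, "pc_scores.csv")
    utils::write.csv(data.frame(specimen = dat$ids, group = dat$group,
                                sex = dat$sex, res$scores),
                     f[length(f)], row.names = FALSE)
    f[length(f) + 1L] <- file.path(config$out_dir, "dispersion.tsv")
    write_tsv_with_header(res$dispersion$summary, f[length(f)], hdr)
    files <- f
  }
  res$files <- files
  res
}
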