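#' Configuration for the haplotype alignment simulator
#'
#' The generator emulates the lineage structure of a phylogeographic
#' mitogenome sample: K discrete lineages arranged on a chain, with fixed
#' numbers of mutations separating consecutive lineages, populations drawing
#' sequences from lineages according to mixture weights, and per-sequence
#' private mutations at previously untouched sites (Poisson, so every
#' downstream expectation has a closed form).
#'
#' @param L alignment length in sites.
#' @param lineage_sep integer vector: mutations between consecutive
#'   lineages (length = number of lineages - 1; empty for one lineage).
#' @param pop_sizes named integer vector of sample sizes per population.
#' @param mixture matrix (populations x lineages) of lineage weights per
#'   population, rows summing to 1; default: each population drawn purely
#'   from lineage \code{(i-1) %% n_lineages + 1}.
#' @param private_rate Poisson mean number of private mutations per
#'   sequence.
#' @param seed RNG seed (mandatory).
#' @return a \code{haplo_sim_config} list.
#' @export
haplo_sim_config <- function(L = 1000L, lineage_sep = c(20L),
                             pop_sizes = c(popA = 10L, popB = 10L),
                             mixture = NULL, private_rate = 0,
                             seed) {
  n_lin <- length(lineage_sep) + 1L
  if (is.null(mixture)) {
    mixture <- matrix(0, length(pop_sizes), n_lin,
                      dimnames = list(names(pop_sizes), NULL))
    for (i in seq_along(pop_sizes))
      mixture[i, (i - 1L) %% n_lin + 1L] <- 1
  }
  stopifnot(nrow(mixture) == length(pop_sizes), ncol(mixture) == n_lin,
            all(abs(rowSums(mixture) - 1) < 1e-12), private_rate >= 0)
  structure(list(L = as.integer(L), lineage_sep = as.integer(lineage_sep),
                 pop_sizes = pop_sizes, mixture = mixture,
                 private_rate = private_rate, seed = seed),
            class = "haplo_sim_config")
}

# Substitute a base at a site with a different one.
mutate_base <- function(base) {
  others <- setdiff(c("A", "C", "G", "T"), base)
  others[sample.int(3L, 1L)]
}

#' Simulate a haplotype alignment with known lineage structure
#'
#' @param cfg a [haplo_sim_config()].
#' @return list with \code{alignment} (a [seal_alignment()]) and
#'   \code{truth}: lineage assignment per sequence, lineage mutation sites,
#'   private mutation sites per sequence, and the config. Deterministic
#'   given the seed.
#' @export
simulate_haplotypes <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$L
  n_lin <- length(cfg$lineage_sep) + 1L
  n_total <- sum(cfg$pop_sizes)
  budget <- sum(cfg$lineage_sep) + 10L * max(1, n_total * max(cfg$private_rate, 1))
  ancestor <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  free_sites <- sample.int(L)  # shuffled pool of yet-unused sites
  take_sites <- function(m) {
    if (m > length(free_sites))
      stop("mutation placement exceeds alignment length L = ", L)
    out <- free_sites[seq_len(m)]
    free_sites <<- free_sites[-seq_len(m)]
    out
  }
  lineages <- vector("list", n_lin)
  lineages[[1]] <- ancestor
  lin_sites <- vector("list", n_lin)
  lin_sites[[1]] <- integer()
  for (l in seq_len(n_lin - 1L)) {
    sites <- take_sites(cfg$lineage_sep[l])
    s <- lineages[[l]]
    for (p in sites) s[p] <- mutate_base(s[p])
    lineages[[l + 1L]] <- s
    lin_sites[[l + 1L]] <- sites
  }
  ids <- character(0); pops <- character(0); seqs <- character(0)
  lin_of <- integer(0)
  private_sites <- list()
  for (i in seq_along(cfg$pop_sizes)) {
    pop <- names(cfg$pop_sizes)[i]
    for (j in seq_len(cfg$pop_sizes[i])) {
      lin <- sample.int(n_lin, 1L, prob = cfg$mixture[i, ])
      s <- lineages[[lin]]
      m <- stats::rpois(1L, cfg$private_rate)
      ps <- if (m > 0) take_sites(m) else integer()
      for (p in ps) s[p] <- mutate_base(s[p])
      id <- sprintf("%s_%02d", pop, j)
      ids <- c(ids, id); pops <- c(pops, pop)
      seqs <- c(seqs, paste(s, collapse = ""))
      lin_of <- c(lin_of, lin)
      private_sites[[id]] <- ps
    }
  }
  list(alignment = seal_alignment(ids, seqs, pops),
       truth = list(lineage = stats::setNames(lin_of, ids),
                    lineage_sites = lin_sites,
                    private_sites = private_sites,
                    config = cfg))
}

#' Deterministic bilaterally symmetric landmark template
#'
#' A fixed skull-like template: \code{n_mid} midline landmarks on the
#' symmetry plane (x = 0) and \code{n_pairs} mirrored left/right pairs.
#' Coordinates are a fixed function of the index (no RNG), roughly
#' elongated along y like a cranium, in mm.
#'
#' @param n_pairs number of bilateral landmark pairs.
#' @param n_mid number of midline landmarks.
#' @return list with \code{template} (k x 3 matrix, k = 2 n_pairs + n_mid)
#'   and \code{pairing} (a [symmetry_pairing()]); landmark order is
#'   left_1..left_P, right_1..right_P, mid_1..mid_M.
#' @export
make_symmetric_template <- function(n_pairs = 12L, n_mid = 7L) {
  k <- 2L * n_pairs + n_mid
  i <- seq_len(n_pairs)
  # left-side points on a half-ellipsoid shell
  left <- cbind(-(20 + 15 * sin(i)),               # lateral
                80 * (i - 1) / max(n_pairs - 1, 1) - 40,  # anteroposterior
                12 * cos(1.7 * i))                 # dorsoventral
  right <- left
  right[, 1] <- -left[, 1]
  j <- seq_len(n_mid)
  mid <- cbind(rep(0, n_mid),
               90 * (j - 1) / max(n_mid - 1, 1) - 45,
               18 * sin(2.1 * j))
  template <- rbind(left, right, mid)
  pairing <- symmetry_pairing(cbind(i, n_pairs + i), 2L * n_pairs + j, k)
  list(template = template, pairing = pairing)
}

#' Project a displacement field onto the symmetric shape subspace
#'
#' Averages a k x 3 displacement with its mirrored, relabelled copy; the
#' result is invariant under [mirror_config()] and therefore survives
#' extraction of the symmetric component unchanged.
#'
#' @param v k x 3 displacement matrix.
#' @param pairing a [symmetry_pairing()].
#' @return k x 3 symmetric displacement.
#' @export
symmetrize_displacement <- function(v, pairing) {
  (v + mirror_config(v, pairing)) / 2
}

# Random proper rotation matrix in 3D.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Configuration for the landmark dataset simulator
#'
#' @param template k x 3 symmetric template (default from
#'   [make_symmetric_template()]); scaled internally to unit centroid size.
#' @param pairing the matching [symmetry_pairing()].
#' @param group_sizes named integer vector of specimens per group.
#' @param group_offset_magnitude Procrustes magnitude of each group's mean
#'   shape offset (single value or named per group; offsets are random but
#'   seed-determined directions in the symmetric shape subspace).
#' @param sex_vector_magnitude Procrustes magnitude of the female-to-male
#'   dimorphism vector (0 disables dimorphism).
#' @param prop_female,prop_unknown sex composition per group.
#' @param allometry_magnitude Procrustes magnitude of the allometric slope
#'   vector per unit log10 centroid size.
#' @param logcs_mean,logcs_sd distribution of log10 centroid size (mm).
#' @param noise_sd isotropic landmark noise standard deviation, in units of
#'   the unit-size shape (> 0).
#' @param group_offsets,sex_vector,slope optional explicit k x 3 effect
#'   matrices (named list / matrix / matrix) overriding the seed-generated
#'   random directions; they are centred and symmetrized but used at the
#'   magnitude supplied.
#' @param seed RNG seed (mandatory).
#' @return a \code{shape_sim_config} list.
#' @export
shape_sim_config <- function(template = NULL, pairing = NULL,
                             group_sizes = c(A = 20L, B = 20L),
                             group_offset_magnitude = 0.02,
                             sex_vector_magnitude = 0.01,
                             prop_female = 0.4, prop_unknown = 0.2,
                             allometry_magnitude = 0.05,
                             logcs_mean = 2.3, logcs_sd = 0.05,
                             noise_sd = 0.005,
                             group_offsets = NULL, sex_vector = NULL,
                             slope = NULL, seed) {
  if (is.null(template)) {
    tpl <- make_symmetric_template()
    template <- tpl$template
    pairing <- tpl$pairing
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(names(group_offset_magnitude)))
    group_offset_magnitude <- stats::setNames(
      rep(group_offset_magnitude, length(group_sizes)), names(group_sizes))
  structure(list(template = template, pairing = pairing,
                 group_sizes = group_sizes,
                 group_offset_magnitude = group_offset_magnitude,
                 sex_vector_magnitude = sex_vector_magnitude,
                 prop_female = prop_female, prop_unknown = prop_unknown,
                 allometry_magnitude = allometry_magnitude,
                 logcs_mean = logcs_mean, logcs_sd = logcs_sd,
                 noise_sd = noise_sd, group_offsets = group_offsets,
                 sex_vector = sex_vector, slope = slope, seed = seed),
            class = "shape_sim_config")
}

# A seed-determined centred symmetric displacement of given magnitude.
random_symmetric_offset <- function(template, pairing, magnitude) {
  v <- matrix(stats::rnorm(length(template)), nrow(template), 3L)
  v <- symmetrize_displacement(v, pairing)
  v <- sweep(v, 2L, colMeans(v))
  v * (magnitude / sqrt(sum(v^2)))
}

#' Simulate a landmark dataset with known group, sex and allometry structure
#'
#' Per specimen: unit-size template + group offset + sex effect + allometric
#' slope times centred log10 centroid size + isotropic noise; then scaled to
#' the drawn centroid size and pushed through a random similarity transform
#' (rotation + translation) to mimic arbitrary digitizer frames.
#'
#' @param cfg a [shape_sim_config()].
#' @return list with \code{dataset} (a [landmark_dataset()]),
#'   \code{pairing}, and \code{truth}: group offsets, sex vector, slope,
#'   per-specimen log centroid size, and the config.
#' @export
simulate_landmarks <- function(cfg) {
  set.seed(cfg$seed)
  tpl <- sweep(cfg$template, 2L, colMeans(cfg$template))
  tpl <- tpl / sqrt(sum(tpl^2))
  k <- nrow(tpl)
  groups <- names(cfg$group_sizes)
  clean <- function(v) {
    v <- symmetrize_displacement(v, cfg$pairing)
    sweep(v, 2L, colMeans(v))
  }
  offsets <- if (!is.null(cfg$group_offsets)) lapply(cfg$group_offsets, clean)
  else {
    o <- lapply(groups, function(g)
      random_symmetric_offset(tpl, cfg$pairing, cfg$group_offset_magnitude[[g]]))
    names(o) <- groups
    o
  }
  sexvec <- if (!is.null(cfg$sex_vector)) clean(cfg$sex_vector)
  else if (cfg$sex_vector_magnitude > 0)
    random_symmetric_offset(tpl, cfg$pairing, cfg$sex_vector_magnitude)
  else matrix(0, k, 3L)
  slope <- if (!is.null(cfg$slope)) clean(cfg$slope)
  else if (cfg$allometry_magnitude > 0)
    random_symmetric_offset(tpl, cfg$pairing, cfg$allometry_magnitude)
  else matrix(0, k, 3L)
  n <- sum(cfg$group_sizes)
  coords <- array(NA_real_, c(k, 3L, n))
  ids <- character(n); grp <- character(n); sex <- character(n)
  logcs <- numeric(n)
  i <- 0L
  for (g in groups) for (j in seq_len(cfg$group_sizes[[g]])) {
    i <- i + 1L
    ids[i] <- sprintf("%s_%03d", g, j); grp[i] <- g
    u <- stats::runif(1)
    sex[i] <- if (u < cfg$prop_unknown) "U"
              else if (u < cfg$prop_unknown +
                         (1 - cfg$prop_unknown) * cfg$prop_female) "F" else "M"
    logcs[i] <- stats::rnorm(1, cfg$logcs_mean, cfg$logcs_sd)
    sex_sign <- switch(sex[i], M = 0.5, F = -0.5, U = sample(c(-0.5, 0.5), 1))
    shape <- tpl + offsets[[g]] + sex_sign * sexvec +
      (logcs[i] - cfg$logcs_mean) * slope +
      matrix(stats::rnorm(3L * k, sd = cfg$noise_sd), k, 3L)
    config <- shape * 10^logcs[i]
    config <- config %*% random_rotation()
    config <- sweep(config, 2L, stats::rnorm(3L, sd = 50), FUN = "+")
    coords[, , i] <- config
  }
  list(dataset = landmark_dataset(coords, ids, grp, sex),
       pairing = cfg$pairing,
       truth = list(template = tpl, offsets = offsets, sex_vector = sexvec,
                    slope = slope, logcs = logcs, config = cfg))
}
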