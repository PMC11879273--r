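#' Landmark dataset container
#'
#' @param coords numeric array of dimension k x 3 x n (landmarks x xyz x
#'   specimens), units mm.
#' @param ids specimen identifiers (unique, length n).
#' @param group group (sampling area) label per specimen.
#' @param sex \code{"F"}, \code{"M"} or \code{"U"} (unknown) per specimen.
#' @return object of class \code{landmark_dataset}.
#' @export
landmark_dataset <- function(coords, ids, group,
                             sex = rep("U", length(ids))) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n <- dim(coords)[3]
  if (length(ids) != n || length(group) != n || length(sex) != n)
    stop("ids, group, sex must match the number of specimens")
  if (anyDuplicated(ids)) stop("duplicated specimen ids")
  if (any(!is.finite(coords))) stop("missing or non-finite landmarks")
  structure(list(coords = coords, ids = as.character(ids),
                 group = as.character(group), sex = as.character(sex),
                 k = dim(coords)[1], n = n),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("landmark_dataset:", x$n, "specimens x", x$k, "landmarks (3D)\n")
  print(table(group = x$group, sex = x$sex))
  invisible(x)
}

#' Read a wide-format landmark CSV
#'
#' Expected columns: \code{specimen,group,sex,x1,y1,z1,...,xK,yK,zK}.
#'
#' @param path CSV file.
#' @return a [landmark_dataset()].
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "group", "sex")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns specimen, group, sex")
  mat <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  if (ncol(mat) %% 3L != 0L) stop("coordinate columns not a multiple of 3")
  k <- ncol(mat) / 3L
  coords <- array(NA_real_, c(k, 3L, nrow(df)))
  for (i in seq_len(nrow(df)))
    coords[, , i] <- matrix(mat[i, ], k, 3L, byrow = TRUE)
  landmark_dataset(coords, df$specimen, df$group, df$sex)
}

#' Write a landmark dataset as wide CSV
#' @param dat a [landmark_dataset()].
#' @param path output CSV.
#' @export
write_landmarks_csv <- function(dat, path) {
  flat <- t(apply(dat$coords, 3L, function(m) as.vector(t(m))))
  colnames(flat) <- paste0(rep(c("x", "y", "z"), dat$k),
                           rep(seq_len(dat$k), each = 3L))
  utils::write.csv(cbind(data.frame(specimen = dat$ids, group = dat$group,
                                    sex = dat$sex), flat),
                   path, row.names = FALSE, quote = FALSE)
  invisible(dat)
}

#' Read a TPS landmark file
#'
#' Minimal TPS reader: LM/LM3= record headers, coordinate rows, ID= lines.
#' Group and sex default to unknown and can be attached afterwards.
#'
#' @param path TPS file with 2D or 3D coordinates.
#' @return a [landmark_dataset()] (2D input gets a zero z coordinate).
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  specs <- list(); ids <- character(); cur <- NULL; id <- NA_character_
  flush <- function() {
    if (is.null(cur)) return()
    specs[[length(specs) + 1L]] <<- do.call(rbind, cur)
    ids[length(ids) + 1L] <<- if (is.na(id)) paste0("spec", length(ids) + 1L) else id
  }
  for (ln in lines) {
    if (grepl("^LM3?=", ln, ignore.case = TRUE)) {
      flush(); cur <- list(); id <- NA_character_
    } else if (grepl("^ID=", ln, ignore.case = TRUE)) {
      id <- sub("^ID=", "", ln, ignore.case = TRUE)
    } else if (grepl("^[-0-9]", ln)) {
      cur[[length(cur) + 1L]] <- as.numeric(strsplit(ln, "\\s+")[[1]])
    }
  }
  flush()
  if (!length(specs)) stop("no landmark records in ", path)
  k <- nrow(specs[[1]])
  coords <- array(0, c(k, 3L, length(specs)))
  for (i in seq_along(specs)) {
    m <- specs[[i]]
    if (nrow(m) != k) stop("record ", i, " has ", nrow(m), " landmarks, expected ", k)
    coords[, seq_len(ncol(m)), i] <- m
  }
  landmark_dataset(coords, ids, rep("unknown", length(specs)))
}

#' Read a bilateral symmetry pairing table
#'
#' Tab-separated, 1-based landmark indices: two columns for left/right
#' pairs, rows with a single column for midline landmarks. Header optional
#' (lines that do not start with a digit are skipped).
#'
#' @param path TSV file.
#' @param k total number of landmarks (for validation).
#' @return object of class \code{symmetry_pairing}: list with \code{pairs}
#'   (m x 2 integer matrix) and \code{midline} (integer vector).
#' @export
read_pairing <- function(path, k) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & grepl("^[0-9]", lines)]
  parts <- strsplit(lines, "\t")
  pairs <- do.call(rbind, lapply(parts[lengths(parts) == 2L],
                                 function(p) as.integer(p)))
  midline <- as.integer(unlist(parts[lengths(parts) == 1L]))
  symmetry_pairing(pairs, midline, k)
}

#' Construct and validate a symmetry pairing
#' @param pairs m x 2 matrix of (left, right) landmark indices.
#' @param midline indices of unpaired midline landmarks.
#' @param k total number of landmarks.
#' @return a \code{symmetry_pairing}.
#' @export
symmetry_pairing <- function(pairs, midline, k) {
  if (is.null(pairs)) pairs <- matrix(integer(), 0, 2)
  all_idx <- c(as.vector(pairs), midline)
  if (anyDuplicated(all_idx) || !setequal(all_idx, seq_len(k)))
    stop("pairing must cover all ", k, " landmarks exactly once")
  structure(list(pairs = pairs, midline = as.integer(midline), k = k),
            class = "symmetry_pairing")
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks to their
#' centroid; invariant to translation and rotation, linear in scale.
#'
#' @param config k x 3 matrix.
#' @return centroid size (> 0).
#' @export
centroid_size <- function(config) {
  centered <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(centered^2))
  if (cs == 0) stop("all landmarks coincident: centroid size undefined")
  cs
}

# Optimal rotation (no reflection) carrying X onto Y: minimizes ||X R - Y||.
procrustes_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes analysis
#'
#' Rohlf-Slice generalized least-squares superimposition: each configuration
#' is centred and scaled to unit centroid size, then iteratively rotated
#' (proper rotations only; reflection is handled exclusively by the symmetry
#' machinery) to the current consensus until the consensus moves less than
#' \code{tol} in Procrustes distance.
#'
#' @param coords k x 3 x n array of raw configurations.
#' @param tol convergence tolerance on the consensus update.
#' @param max_iter maximum number of iterations.
#' @return list of class \code{gpa_result}: \code{aligned} (k x 3 x n array,
#'   unit centroid size), \code{cs} (original centroid sizes), \code{mean}
#'   (consensus, unit centroid size), \code{iterations}, \code{delta}.
#' @export
gpa <- function(coords, tol = 1e-8, max_iter = 100L) {
  n <- dim(coords)[3]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  cs <- apply(coords, 3L, centroid_size)
  aligned <- coords
  for (i in seq_len(n)) {
    c0 <- sweep(coords[, , i], 2L, colMeans(coords[, , i]))
    aligned[, , i] <- c0 / cs[i]
  }
  ref <- aligned[, , 1]
  for (i in seq_len(n)) aligned[, , i] <-
    aligned[, , i] %*% procrustes_rotation(aligned[, , i], ref)
  mshape <- apply(aligned, c(1, 2), mean)
  mshape <- mshape / sqrt(sum(mshape^2))
  delta <- Inf
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) aligned[, , i] <-
      aligned[, , i] %*% procrustes_rotation(aligned[, , i], mshape)
    new_mean <- apply(aligned, c(1, 2), mean)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mshape)^2))
    mshape <- new_mean
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("GPA did not converge in ", max_iter, " iterations (delta = ",
         signif(delta, 3), ")")
  structure(list(aligned = aligned, cs = cs, mean = mshape,
                 iterations = it, delta = delta),
            class = "gpa_result")
}

#' Mirror a configuration and swap paired landmark labels
#'
#' Reflects the x axis and relabels left/right landmark pairs, producing the
#' mirror copy used by the object-symmetry superimposition.
#'
#' @param config k x 3 matrix.
#' @param pairing a [symmetry_pairing()].
#' @return k x 3 matrix.
#' @export
mirror_config <- function(config, pairing) {
  m <- config
  m[, 1] <- -m[, 1]
  perm <- seq_len(nrow(config))
  perm[pairing$pairs[, 1]] <- pairing$pairs[, 2]
  perm[pairing$pairs[, 2]] <- pairing$pairs[, 1]
  m[perm, , drop = FALSE]
}

#' Symmetric component of shape variation
#'
#' Object-symmetry treatment for bilaterally symmetric structures: each
#' configuration and its mirrored, relabelled copy are superimposed jointly
#' by GPA, and the symmetric component of each specimen is the average of
#' its two aligned copies. Downstream analyses consume these symmetric
#' shapes, removing the redundancy (and the asymmetric variation) of
#' paired landmarks.
#'
#' @param dat a [landmark_dataset()].
#' @param pairing a [symmetry_pairing()].
#' @param tol,max_iter passed to [gpa()].
#' @return list of class \code{symmetric_shapes}: \code{shapes} (k x 3 x n
#'   symmetric component per specimen), \code{cs} (centroid sizes of the raw
#'   configurations), \code{mean}, \code{ids}, \code{group}, \code{sex},
#'   \code{gpa} (the joint superimposition).
#' @export
symmetric_component <- function(dat, pairing, tol = 1e-8, max_iter = 100L) {
  if (pairing$k != dat$k) stop("pairing does not match landmark count")
  n <- dat$n; k <- dat$k
  both <- array(NA_real_, c(k, 3L, 2L * n))
  both[, , seq_len(n)] <- dat$coords
  for (i in seq_len(n))
    both[, , n + i] <- mirror_config(dat$coords[, , i], pairing)
  g <- gpa(both, tol = tol, max_iter = max_iter)
  shapes <- array(NA_real_, c(k, 3L, n))
  for (i in seq_len(n))
    shapes[, , i] <- (g$aligned[, , i] + g$aligned[, , n + i]) / 2
  structure(list(shapes = shapes, cs = g$cs[seq_len(n)],
                 mean = apply(shapes, c(1, 2), mean),
                 ids = dat$ids, group = dat$group, sex = dat$sex, gpa = g),
            class = "symmetric_shapes")
}

# Flatten k x 3 x n array to n x 3k matrix (x1,y1,z1,x2,...) and back.
flatten_shapes <- function(arr) {
  t(apply(arr, 3L, function(m) as.vector(t(m))))
}

#' Allometry correction by regression on log centroid size
#'
#' Pooled multivariate linear regression of every shape coordinate on
#' log10(centroid size); the residuals are the size-corrected shapes used in
#' all downstream comparisons. If centroid size does not vary the regression
#' is skipped with a warning and centred shapes are returned.
#'
#' @param shapes k x 3 x n array (or n x 3k matrix) of aligned shapes.
#' @param cs centroid sizes (length n, > 0).
#' @return list of class \code{allometry_fit}: \code{residuals} (n x 3k),
#'   \code{slope} (3k, per unit log10 CS), \code{intercept}, \code{logcs},
#'   \code{mean_shape} (row mean added back for visualisation).
#' @export
allometry_residuals <- function(shapes, cs) {
  X <- if (length(dim(shapes)) == 3L) flatten_shapes(shapes) else as.matrix(shapes)
  if (nrow(X) < 3L) stop("need at least 3 specimens")
  if (any(cs <= 0)) stop("centroid sizes must be positive")
  logcs <- log10(cs)
  mu <- colMeans(X)
  if (stats::var(logcs) == 0) {
    warning("no variance in log centroid size; returning centred shapes")
    res <- sweep(X, 2L, mu)
    slope <- rep(0, ncol(X))
  } else {
    xc <- logcs - mean(logcs)
    slope <- as.vector(crossprod(sweep(X, 2L, mu), xc) / sum(xc^2))
    res <- sweep(X, 2L, mu) - outer(xc, slope)
  }
  structure(list(residuals = res, slope = slope, intercept = mu,
                 logcs = logcs, mean_shape = mu),
            class = "allometry_fit")
}

#' Principal component analysis of shape residuals
#'
#' Covariance-matrix PCA of the (already centred) residual shapes, with a
#' fixed sign convention: the loading of largest magnitude on each component
#' is positive, so scores are reproducible across platforms.
#'
#' @param residuals n x 3k matrix (e.g. from [allometry_residuals()]).
#' @return list of class \code{shape_pca}: \code{scores}, \code{loadings},
#'   \code{eigenvalues}, \code{var_frac}, \code{cum_var}.
#' @export
shape_pca <- function(residuals) {
  if (nrow(residuals) < 3L) stop("need at least 3 specimens")
  pc <- stats::prcomp(residuals, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(scores = pc$x, loadings = pc$rotation, eigenvalues = ev,
                 var_frac = ev / sum(ev), cum_var = cumsum(ev) / sum(ev)),
            class = "shape_pca")
}

# Group means and pooled within-group covariance of a score matrix.
group_moments <- function(scores, labels) {
  gs <- split(seq_len(nrow(scores)), labels)
  means <- lapply(gs, function(ix) colMeans(scores[ix, , drop = FALSE]))
  p <- ncol(scores)
  pooled <- matrix(0, p, p)
  df <- 0L
  for (ix in gs) {
    if (length(ix) < 2L) next
    xc <- sweep(scores[ix, , drop = FALSE], 2L, colMeans(scores[ix, , drop = FALSE]))
    pooled <- pooled + crossprod(xc)
    df <- df + length(ix) - 1L
  }
  if (df == 0L) stop("no group has 2 or more members")
  list(means = means, cov = pooled / df, df = df)
}

#' Jackknife (leave-one-out) Mahalanobis classification
#'
#' Strict Lachenbruch cross-validation of canonical-variates / discriminant
#' classification: for every specimen, group means and the pooled
#' within-group covariance are re-estimated without it, and it is assigned
#' to the group whose mean is closest in Mahalanobis distance (equal
#' priors; ties broken by group declaration order).
#'
#' @param scores n x p score matrix (typically the first 10 PCs).
#' @param labels group label per specimen (>= 2 groups, each with >= 2
#'   members).
#' @param groups optional declared group order (default: order of first
#'   appearance).
#' @return object of class \code{classification_result}: \code{confusion}
#'   (origin x assignment counts), \code{rates} (per-group success),
#'   \code{overall}, \code{assigned}, \code{n}.
#' @export
jackknife_classify <- function(scores, labels, groups = unique(labels)) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  keep <- labels %in% groups
  scores <- scores[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(table(labels)[groups] < 2L)) stop("every group needs >= 2 members")
  n <- nrow(scores)
  assigned <- character(n)
  for (i in seq_len(n)) {
    gm <- group_moments(scores[-i, , drop = FALSE], labels[-i])
    ic <- tryCatch(solve(gm$cov), error = function(e)
      stop("singular pooled covariance; use fewer PCs"))
    d2 <- vapply(groups, function(g) {
      dv <- scores[i, ] - gm$means[[g]]
      as.numeric(dv %*% ic %*% dv)
    }, numeric(1))
    assigned[i] <- groups[which.min(d2)]
  }
  confusion <- table(origin = factor(labels, groups),
                     assignment = factor(assigned, groups))
  rates <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = unclass(confusion), rates = rates,
                 overall = mean(assigned == labels), assigned = assigned,
                 n = n),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("jackknife classification: %.1f%% overall success (n = %d)\n",
              100 * x$overall, x$n))
  print(x$confusion)
  invisible(x)
}

#' Pairwise two-group jackknife classification
#'
#' [jackknife_classify()] restricted to two groups — the linear-discriminant
#' analogue used for pairwise diagnosability (percent diagnosability, PD).
#'
#' @inheritParams jackknife_classify
#' @param groupA,groupB the two group labels.
#' @return a \code{classification_result}.
#' @export
pairwise_classify <- function(scores, labels, groupA, groupB) {
  jackknife_classify(scores, labels, groups = c(groupA, groupB))
}

#' Mahalanobis distance between two group means
#'
#' Distance between group mean score vectors in the metric of the pooled
#' within-group covariance. By default the covariance is pooled over all
#' groups present (the canonical-variates convention); set
#' \code{pool = c(gA, gB)} to pool over the two groups only.
#'
#' @inheritParams jackknife_classify
#' @param gA,gB group labels.
#' @param pool groups over which to pool the covariance.
#' @return non-negative distance.
#' @export
mahalanobis_distance <- function(scores, labels, gA, gB,
                                 pool = unique(labels)) {
  scores <- as.matrix(scores)
  keep <- labels %in% pool
  gm <- group_moments(scores[keep, , drop = FALSE], labels[keep])
  dv <- gm$means[[gA]] - gm$means[[gB]]
  ic <- tryCatch(solve(gm$cov), error = function(e)
    stop("singular pooled covariance; use fewer PCs"))
  sqrt(as.numeric(dv %*% ic %*% dv))
}

#' Procrustes distance between two shapes
#'
#' Euclidean distance in the common aligned shape space: the square root of
#' the summed squared coordinate differences.
#'
#' @param a,b shapes as k x 3 matrices or flattened vectors, already in the
#'   same superimposition.
#' @return non-negative distance.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Two-sample Hotelling's T-squared test
#'
#' T2 = (nA nB)/(nA + nB) d' S^-1 d with pooled covariance S, transformed to
#' F = T2 (nA + nB - p - 1) / (p (nA + nB - 2)) on (p, nA + nB - p - 1)
#' degrees of freedom.
#'
#' @inheritParams mahalanobis_distance
#' @return list of class \code{hotelling_result}: \code{t2}, \code{f},
#'   \code{df1}, \code{df2}, \code{p_value}, \code{nA}, \code{nB}.
#' @export
hotelling_t2 <- function(scores, labels, gA, gB) {
  scores <- as.matrix(scores)
  xa <- scores[labels == gA, , drop = FALSE]
  xb <- scores[labels == gB, , drop = FALSE]
  nA <- nrow(xa); nB <- nrow(xb); p <- ncol(scores)
  if (nA + nB - 2L <= p)
    stop("insufficient degrees of freedom: nA + nB - 2 must exceed p")
  S <- ((nA - 1) * stats::cov(xa) + (nB - 1) * stats::cov(xb)) / (nA + nB - 2)
  dv <- colMeans(xa) - colMeans(xb)
  t2 <- (nA * nB) / (nA + nB) * as.numeric(dv %*% solve(S, dv))
  f <- t2 * (nA + nB - p - 1) / (p * (nA + nB - 2))
  structure(list(t2 = t2, f = f, df1 = p, df2 = nA + nB - p - 1,
                 p_value = stats::pf(f, p, nA + nB - p - 1, lower.tail = FALSE),
                 nA = nA, nB = nB),
            class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("Hotelling T2 = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
              x$t2, x$df1, x$df2, x$f, x$p_value))
  invisible(x)
}

#' Linear discriminant vector between two groups
#'
#' Direction S_pooled^-1 (mean_A - mean_B) in the score space, the vector
#' whose angle to other discriminant vectors measures independence of shape
#' contrasts (e.g. sexual dimorphism vs geography).
#'
#' @inheritParams mahalanobis_distance
#' @param pool groups over which to pool the covariance (default: the two
#'   groups themselves).
#' @return numeric vector of length p.
#' @export
discriminant_vector <- function(scores, labels, gA, gB, pool = c(gA, gB)) {
  scores <- as.matrix(scores)
  keep <- labels %in% pool
  gm <- group_moments(scores[keep, , drop = FALSE], labels[keep])
  as.vector(solve(gm$cov, gm$means[[gA]] - gm$means[[gB]]))
}

#' Angle between two shape-difference vectors
#'
#' @param vA,vB non-zero numeric vectors in the same space.
#' @return angle in degrees, in [0, 180].
#' @export
vector_angle <- function(vA, vB) {
  na <- sqrt(sum(vA^2)); nb <- sqrt(sum(vB^2))
  if (na == 0 || nb == 0) stop("zero vector has no direction")
  acos(max(-1, min(1, sum(vA * vB) / (na * nb)))) * 180 / pi
}

#' Within-group shape dispersion
#'
#' Procrustes distance of every specimen to its own group mean shape, with
#' pairwise t tests comparing dispersion levels between groups (Welch by
#' default; \code{pooled_var = TRUE} for the classical equal-variance
#' Student test). The same machinery serves centroid-size comparisons by
#' passing sizes as a one-column matrix.
#'
#' @param shapes k x 3 x n array or n x q matrix of aligned shapes.
#' @param labels group label per specimen (each group >= 2 members).
#' @param pooled_var use pooled-variance Student t tests.
#' @return list of class \code{dispersion_stats}: \code{distances}
#'   (per-specimen), \code{summary} (per-group mean/sd/median/quartiles),
#'   \code{tests} (pairwise t-test table).
#' @export
dispersion_stats <- function(shapes, labels, pooled_var = FALSE) {
  X <- if (length(dim(shapes)) == 3L) flatten_shapes(shapes) else as.matrix(shapes)
  labels <- as.character(labels)
  groups <- unique(labels)
  dist_to_mean <- numeric(nrow(X))
  for (g in groups) {
    ix <- which(labels == g)
    mu <- colMeans(X[ix, , drop = FALSE])
    dist_to_mean[ix] <- sqrt(rowSums(sweep(X[ix, , drop = FALSE], 2L, mu)^2))
  }
  summ <- do.call(rbind, lapply(groups, function(g) {
    d <- dist_to_mean[labels == g]
    q <- stats::quantile(d, c(0.25, 0.5, 0.75))
    data.frame(group = g, n = length(d), mean = mean(d), sd = stats::sd(d),
               q25 = q[[1]], median = q[[2]], q75 = q[[3]],
               stringsAsFactors = FALSE)
  }))
  tests <- list()
  if (length(groups) > 1L)
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      tt <- stats::t.test(dist_to_mean[labels == groups[i]],
                          dist_to_mean[labels == groups[j]],
                          var.equal = pooled_var)
      tests[[length(tests) + 1L]] <-
        data.frame(group_a = groups[i], group_b = groups[j],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value, stringsAsFactors = FALSE)
    }
  structure(list(distances = data.frame(label = labels, distance = dist_to_mean),
                 summary = summ,
                 tests = if (length(tests)) do.call(rbind, tests) else NULL),
            class = "dispersion_stats")
}
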