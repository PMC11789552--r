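# Signed weighted coexpression network: biweight midcorrelation, scale-free
# soft-threshold selection, topological overlap, static-cut module detection,
# eigengenes, merging and membership filtering.

# Biweight transform of one vector: median-centred, biweight-downweighted,
# ready for cross products. Falls back to mean-centring when mad = 0.
.bicor_prep <- function(x) {
  med <- stats::median(x)
  madx <- stats::mad(x, constant = 1)
  if (madx == 0) {
    xt <- x - mean(x)
  } else {
    u <- (x - med) / (9 * madx)
    w <- (1 - u ^ 2) ^ 2 * (abs(u) < 1)
    xt <- w * (x - med)
  }
  nrm <- sqrt(sum(xt ^ 2))
  if (nrm == 0) rep(0, length(x)) else xt / nrm
}

#' Biweight midcorrelation
#'
#' Robust correlation using median/MAD-based biweights: observations beyond
#' nine MADs from the median get zero weight, others are smoothly
#' down-weighted. Variables with zero MAD fall back to Pearson centring.
#'
#' @param x numeric vector, or a matrix with variables in columns.
#' @param y optional second vector (ignored when `x` is a matrix).
#' @return A correlation in `[-1, 1]`, or the full bicor matrix of the
#'   columns of `x`.
#' @export
bicor <- function(x, y = NULL) {
  if (is.matrix(x)) {
    if (nrow(x) < 4) stop("bicor needs length >= 4")
    xt <- apply(x, 2, .bicor_prep)
    r <- crossprod(xt)
    r[r > 1] <- 1; r[r < -1] <- -1
    diag(r) <- 1
    return(r)
  }
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 4) stop("bicor needs length >= 4")
  r <- sum(.bicor_prep(x) * .bicor_prep(y))
  min(max(r, -1), 1)
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^power`: the standard signed transform, mapping
#' strong negative correlations to near-zero adjacency.
#'
#' @param cors correlation matrix.
#' @param power soft-threshold power.
#' @return Adjacency matrix with unit diagonal.
#' @export
signed_adjacency <- function(cors, power) {
  a <- ((1 + cors) / 2) ^ power
  diag(a) <- 1
  a
}

# Scale-free topology fit index of a connectivity vector: R^2 of
# log10 p(k) ~ log10 k over 10 equal-width connectivity bins (the binning
# convention of the coexpression framework this mirrors), signed against
# the slope so that increasing p(k) counts as a poor fit.
.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2 || diff(range(k)) == 0) return(NA_real_)
  bin <- cut(k, n_bins, labels = FALSE)
  cnt <- tabulate(bin, n_bins)
  keep <- which(cnt > 0)
  if (length(keep) < 2) return(NA_real_)
  mean_k <- vapply(keep, function(b) mean(k[bin == b]), numeric(1))
  p <- cnt[keep] / sum(cnt)
  ok <- mean_k > 0
  if (sum(ok) < 2) return(NA_real_)
  fit <- stats::lm(log10(p[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Select the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the signed adjacency is formed and the scale-free
#' topology fit index computed from the connectivity distribution; the
#' selected power is the first whose fit index reaches
#' `params$scale_free_target` (falling back, with a warning, to the best
#' fitting candidate if none does).
#'
#' @param expr expression matrix with samples in rows, genes in columns.
#' @param params a [network_params()].
#' @param cors optional precomputed correlation matrix.
#' @return List with `power` and the per-candidate `fit_table`
#'   (`power`, `fit`, `mean_k`).
#' @export
pick_soft_threshold <- function(expr, params = network_params(),
                                cors = NULL) {
  if (ncol(expr) < 30) stop("need >= 30 genes to assess scale-free fit")
  cors <- cors %||% bicor(expr)
  b <- (1 + cors) / 2
  diag(b) <- 1
  powers <- sort(params$powers)
  fit <- mean_k <- numeric(length(powers))
  cur <- b
  cur_pow <- 1
  for (i in seq_along(powers)) {
    p <- powers[i]
    if (p == cur_pow) {
      a <- cur
    } else if (abs(p - round(p)) < 1e-9 && p > cur_pow &&
               abs(cur_pow - round(cur_pow)) < 1e-9) {
      for (j in seq_len(round(p) - round(cur_pow))) cur <- cur * b
      cur_pow <- p
      a <- cur
    } else {
      a <- b ^ p
    }
    k <- colSums(a) - 1
    fit[i] <- .scale_free_fit(k)
    mean_k[i] <- mean(k)
  }
  tab <- data.frame(power = powers, fit = fit, mean_k = mean_k)
  ok <- which(!is.na(fit) & fit >= params$scale_free_target)
  if (length(ok)) {
    power <- powers[ok[1]]
  } else {
    warning("no candidate power reaches the scale-free target; ",
            "using the best-fitting one")
    power <- powers[which.max(fit)]
  }
  list(power = power, fit_table = tab)
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over third parties `u != i, j`; unit diagonal. Two genes share high
#' topological overlap when they are strongly connected to the same
#' neighbourhood.
#'
#' @param adjacency symmetric adjacency matrix, entries in `[0, 1]`, unit
#'   diagonal.
#' @return The TOM matrix (symmetric, entries in `[0, 1]`).
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-8))
    stop("adjacency must be symmetric")
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency entries must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 1
  l <- a %*% a
  k <- colSums(a) - 1
  kmin <- outer(k, k, pmin)
  tom <- (l - a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  tom
}

#' Detect coexpression modules by recursive static tree cut
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' `1 - TOM`, cut just below the `cut_quantile` quantile of merge heights.
#' Because distinct tight modules can join each other below the heights at
#' which unclustered genes agglomerate, the cut is applied recursively: each
#' cluster is re-clustered and split at its top join as long as both halves
#' still hold `min_module_size` genes. This deliberately over-splits;
#' [merge_and_filter()] re-merges branches whose eigengenes correlate above
#' the merge threshold and dissolves incoherent remnants, so the final
#' module set is governed by the eigengene-merge and kME rules. Clusters
#' smaller than `min_module_size` dissolve into module 0 (unassigned);
#' surviving modules are renumbered by decreasing size.
#'
#' @param tom TOM similarity matrix with gene names.
#' @param params a [network_params()].
#' @return List with `assignment` (named integer vector, 0 = unassigned),
#'   `tree` (the [stats::hclust] object) and `cut_height`.
#' @export
detect_modules <- function(tom, params = network_params()) {
  d <- 1 - tom
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  h <- stats::quantile(hc$height, params$cut_quantile, names = FALSE)
  n <- ncol(tom)
  min_size <- params$min_module_size
  mg <- hc$merge
  sizes <- integer(max(n - 1, 1))
  for (i in seq_len(n - 1))
    sizes[i] <- sum(ifelse(mg[i, ] < 0, 1L, sizes[pmax(mg[i, ], 1L)]))
  node_size <- function(j) if (j < 0) 1L else sizes[j]
  cl <- integer(n)
  nxt <- 0L
  # assign every leaf under node j to a fresh cluster id (iterative DFS)
  emit <- function(j) {
    nxt <<- nxt + 1L
    stack <- j
    while (length(stack)) {
      k <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (k < 0) cl[-k] <<- nxt else stack <- c(stack, mg[k, 1], mg[k, 2])
    }
  }
  if (n == 1) {
    cl <- 1L
  } else {
    # walk down from the root: joins at or above the cut height are never
    # modules; below it, keep descending while both branches could still be
    # modules, peel off under-sized stragglers, and emit a cluster when no
    # further admissible split exists
    stack <- n - 1L
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (j < 0) { emit(j); next }
      a <- mg[j, 1]; b <- mg[j, 2]
      if (hc$height[j] >= h - 1e-10) {
        stack <- c(stack, a, b)
      } else {
        na <- node_size(a); nb <- node_size(b)
        if (na >= min_size && nb >= min_size) {
          stack <- c(stack, a, b)
        } else if (na >= min_size || nb >= min_size) {
          # one under-sized branch: peel it off only when the join lies
          # closer to the cut height than to the big branch's own top --
          # i.e. the small branch is a noise-regime straggler, not part of
          # the module's interior height continuum
          big <- if (na >= min_size) a else b
          small <- if (na >= min_size) b else a
          big_top <- hc$height[big]
          if (hc$height[j] > (big_top + h) / 2) {
            emit(small); stack <- c(stack, big)
          } else emit(j)
        } else emit(j)
      }
    }
  }
  sz <- table(cl)
  cl[cl %in% as.integer(names(sz)[sz < min_size])] <- 0L
  assignment <- relabel_modules(cl)
  names(assignment) <- rownames(tom) %||% colnames(tom)
  list(assignment = assignment, tree = hc, cut_height = h)
}

# Renumber non-zero module ids by decreasing size (1 = largest).
relabel_modules <- function(cl) {
  ids <- setdiff(unique(cl), 0L)
  if (!length(ids)) return(integer(length(cl)))
  sizes <- vapply(ids, function(i) sum(cl == i), numeric(1))
  map <- stats::setNames(seq_along(ids), ids[order(-sizes)])
  out <- integer(length(cl))
  nz <- cl != 0L
  out[nz] <- map[as.character(cl[nz])]
  out
}

#' Module eigengenes
#'
#' Genes are z-scored across samples; each module's eigengene is the
#' unit-norm first left singular vector (first principal component sample
#' scores) of its standardised expression, sign-oriented to correlate
#' positively with the module's mean standardised expression. Module 0 (the
#' unassigned genes) is retained as a pseudo-module.
#'
#' @param expr expression matrix, samples in rows, genes in columns.
#' @param assignment named integer module assignment (0 = unassigned).
#' @return Matrix samples x modules, columns named `mod00`, `mod01`, ...
#' @export
module_eigengenes <- function(expr, assignment) {
  z <- scale(expr)
  z[, !is.finite(colSums(z))] <- 0
  ids <- sort(unique(assignment))
  e <- vapply(ids, function(id) {
    x <- z[, assignment == id, drop = FALSE]
    if (ncol(x) == 1) {
      v <- x[, 1]
      nrm <- sqrt(sum(v ^ 2))
      return(if (nrm == 0) v else v / nrm)
    }
    u <- svd(x, nu = 1, nv = 0)$u[, 1]
    mns <- rowMeans(x)
    if (sum(u * mns) < 0) u <- -u
    u
  }, numeric(nrow(expr)))
  colnames(e) <- module_label(ids)
  rownames(e) <- rownames(expr)
  e
}

#' Merge related modules and filter genes by module membership
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' while it exceeds `merge_correlation` (recomputing eigengenes after each
#' merge), then unassigns genes whose module membership (kME, the
#' correlation between a gene's expression and its own module eigengene)
#' falls below `kme_threshold`, and recomputes eigengenes once more.
#'
#' @param assignment named integer module assignment.
#' @param expr expression matrix, samples in rows, genes in columns.
#' @param params a [network_params()].
#' @return An object of class `module_set`: list with `assignment`,
#'   `eigengenes` (including the `mod00` pseudo-module), `kme`,
#'   `n_modules`, `params`.
#' @export
merge_and_filter <- function(assignment, expr, params = network_params()) {
  stopifnot(length(assignment) == ncol(expr))
  repeat {
    ids <- setdiff(sort(unique(assignment)), 0L)
    if (length(ids) < 2) break
    e <- module_eigengenes(expr, assignment)
    e <- e[, module_label(ids), drop = FALSE]
    ec <- stats::cor(e)
    diag(ec) <- -Inf
    best <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (max(ec) <= params$merge_correlation) break
    from <- ids[max(best)]
    to <- ids[min(best)]
    assignment[assignment == from] <- to
  }
  z <- scale(expr)
  z[, !is.finite(colSums(z))] <- 0
  # kME filter iterated to a fixed point: dropping weak genes shifts the
  # eigengene, which can push further genes below the threshold; the
  # minimum-size rule applies to the filtered modules as well
  for (it in 1:20) {
    e <- module_eigengenes(expr, assignment)
    own <- e[, module_label(assignment), drop = FALSE]
    kme <- colSums(z * own) / sqrt(colSums(z ^ 2) * colSums(own ^ 2))
    kme[!is.finite(kme)] <- 0
    bad <- assignment != 0L & kme < params$kme_threshold
    sizes <- table(assignment[assignment != 0L])
    drop_ids <- as.integer(names(sizes)[sizes < params$min_module_size])
    bad <- bad | assignment %in% drop_ids
    if (!any(bad)) break
    assignment[bad] <- 0L
  }
  assignment <- stats::setNames(relabel_modules(assignment),
                                names(assignment))
  e <- module_eigengenes(expr, assignment)
  own <- e[, module_label(assignment), drop = FALSE]
  kme <- colSums(z * own) / sqrt(colSums(z ^ 2) * colSums(own ^ 2))
  kme[!is.finite(kme)] <- 0
  names(kme) <- names(assignment)
  structure(list(assignment = assignment, eigengenes = e, kme = kme,
                 n_modules = length(setdiff(unique(assignment), 0L)),
                 params = params),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("Coexpression module set:", x$n_modules, "modules +",
      sum(x$assignment == 0), "unassigned genes (mod00) of",
      length(x$assignment), "\n")
  sizes <- table(module_label(x$assignment))
  print(sizes)
  invisible(x)
}

#' Build a signed coexpression network and detect modules
#'
#' End-to-end driver: biweight midcorrelation on the moderated-log
#' expression matrix, soft-threshold selection by scale-free fit, signed
#' adjacency, topological overlap, static-cut module detection, merging and
#' kME filtering.
#'
#' @param norm normalised expression matrix, genes in rows, samples in
#'   columns (the package-wide convention; transposed internally).
#' @param params a [network_params()].
#' @param power optional fixed soft-threshold power (skips selection).
#' @return A `module_set` with extra fields `power` and `fit_table`.
#' @export
coexpression_modules <- function(norm, params = network_params(),
                                 power = NULL) {
  expr <- t(norm)
  cors <- bicor(expr)
  fit_table <- NULL
  if (is.null(power)) {
    st <- pick_soft_threshold(expr, params, cors = cors)
    power <- st$power
    fit_table <- st$fit_table
  }
  a <- signed_adjacency(cors, power)
  tom <- tom_similarity(a)
  det <- detect_modules(tom, params)
  ms <- merge_and_filter(det$assignment, expr, params)
  ms$power <- power
  ms$fit_table <- fit_table
  ms$cut_height <- det$cut_height
  ms
}
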