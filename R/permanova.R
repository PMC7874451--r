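#' Restricted permutation scheme for repeated-measures PERMANOVA
#'
#' Longitudinal shape data are repeated measures: observations are
#' exchangeable within a subject (stage labels) but subjects, not
#' observations, are the exchangeable units for a between-subject factor.
#' The scheme records the subject blocks and, per model term, whether its
#' null distribution is built from within-subject shuffles of the stage
#' labels or from subject-level permutation of the group labels.
#'
#' @param blocks character/factor vector of subject ids, one per observation.
#' @param n_perms number of random permutations (>= 1). When the restricted
#'   permutation group for a term has at most \code{enumerate_limit}
#'   elements, exhaustive enumeration is used instead and \code{n_perms} is
#'   ignored for that term.
#' @param seed integer seed controlling permutation sampling.
#' @param rules named character vector mapping terms to
#'   \code{"within_subject"} or \code{"between_subject"}. The default uses
#'   within-subject shuffles for \code{stage} and \code{stage:group} and
#'   subject-level shuffles for \code{group}; set all entries to
#'   \code{"within_subject"} for the single-rule mode.
#' @param enumerate_limit maximum permutation-group size for exhaustive
#'   enumeration (default 1024).
#' @return Object of class \code{permutation_scheme}.
#' @export
permutation_scheme <- function(blocks, n_perms = 10000L, seed = 1L,
                               rules = c(stage = "within_subject",
                                         group = "between_subject",
                                         `stage:group` = "within_subject"),
                               enumerate_limit = 1024L) {
  if (n_perms < 1L) stop("n_perms must be >= 1")
  if (!all(rules %in% c("within_subject", "between_subject")))
    stop("rules must be 'within_subject' or 'between_subject'")
  structure(list(blocks = as.character(blocks), n_perms = as.integer(n_perms),
                 seed = as.integer(seed), rules = rules,
                 enumerate_limit = as.integer(enumerate_limit)),
            class = "permutation_scheme")
}

# Gower-centered inner-product matrix of a distance matrix
gower_center <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  sweep(sweep(a, 1L, rm), 2L, rm) + mean(a)
}

# full indicator matrix of a factor (rank handled downstream by QR)
indicator <- function(f) {
  f <- as.factor(f)
  m <- matrix(0, length(f), nlevels(f))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

# tr(H G) for the hat matrix of X, via an orthonormal basis
proj_trace <- function(qrX, G) {
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  sum(Q * (G %*% Q))
}

# Sequential (Type I) sums of squares of the Gower matrix for the nested
# model sequence 1, 1+stage, 1+stage+group, 1+stage+group+stage:group.
# Returns per-term SS/df plus residual and total.
seq_ss <- function(G, stage, group, terms) {
  n <- nrow(G)
  X <- matrix(1, n, 1L)
  qx <- qr(X)
  cum <- proj_trace(qx, G)
  rank_prev <- qx$rank
  ss <- df <- setNames(numeric(length(terms)), terms)
  for (tm in terms) {
    Xt <- switch(tm,
                 stage = indicator(stage),
                 group = indicator(group),
                 `stage:group` = indicator(interaction(stage, group, drop = TRUE)),
                 stop("unknown model term: ", tm))
    X <- cbind(X, Xt)
    qx <- qr(X)
    cum_new <- proj_trace(qx, G)
    ss[tm] <- cum_new - cum
    df[tm] <- qx$rank - rank_prev
    cum <- cum_new
    rank_prev <- qx$rank
  }
  total <- sum(diag(G))
  list(ss = ss, df = df, ss_res = total - cum, df_res = n - rank_prev,
       ss_total = total, df_total = n - 1L)
}

# ---- permutation machinery ----------------------------------------------

# list of per-block index positions
block_index <- function(blocks) split(seq_along(blocks), blocks)

# size of the within-subject permutation group
within_group_size <- function(bi) prod(factorial(lengths(bi)))

# all permutations of 1..n (n small)
perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L))
    for (i in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}

# enumerate all within-subject observation permutations (index vectors)
enumerate_within <- function(bi, n) {
  per_block <- lapply(bi, function(ix) lapply(perms_of(length(ix)), function(p) ix[p]))
  combos <- Reduce(function(acc, blk) {
    out <- list()
    for (a in acc) for (b in blk) out[[length(out) + 1L]] <- c(a, b)
    out
  }, per_block, accumulate = FALSE, right = FALSE, init = list(integer(0)))
  lapply(combos, function(flat) {
    pi <- integer(n)
    pi[unlist(bi, use.names = FALSE)] <- flat
    pi
  })
}

# one random within-subject observation permutation
sample_within <- function(bi, n) {
  pi <- seq_len(n)
  for (ix in bi) if (length(ix) > 1L) pi[ix] <- ix[sample.int(length(ix))]
  pi
}

# permuted group labels from a permutation of subjects
permute_group_labels <- function(group, blocks, subj_perm, subjects) {
  g_of_subject <- group[match(subjects, blocks)]
  new_g <- g_of_subject[subj_perm]
  names(new_g) <- subjects
  factor(new_g[blocks], levels = levels(as.factor(group)))
}

#' Coefficient of partial determination
#'
#' Partial R-squared of a model term: the term's sum of squares relative to
#' that sum of squares plus the full-model residual sum of squares. For
#' orthogonal designs this equals the reduced-versus-full-model formulation
#' (SSE_reduced - SSE_full) / SSE_reduced.
#'
#' @param ss_term term sum of squares (>= 0).
#' @param ss_residual full-model residual sum of squares (>= 0).
#' @return Partial R-squared in [0, 1].
#' @export
partial_r2 <- function(ss_term, ss_residual) {
  if (any(ss_term < -1e-12) || any(ss_residual < -1e-12))
    stop("sums of squares must be non-negative")
  denom <- ss_term + ss_residual
  if (any(denom <= 0)) stop("partial R2 undefined: SS_term + SS_residual is zero")
  ss_term / denom
}

#' Distance-matrix PERMANOVA with restricted permutations
#'
#' Permutational MANOVA of a distance matrix for the repeated-measures model
#' \code{stage + group + stage:group} with sequential (Type I) sums of
#' squares, computed from the Gower-centered distance matrix via projection
#' matrices. Significance uses restricted permutations: within-subject
#' shuffles of the stage labels for the stage and interaction terms and
#' subject-level permutation of the group labels for the group term (per the
#' scheme's rules). Empirical p-values are the probability that a permuted
#' pseudo-F is greater than or equal to the observed one, with the identity
#' permutation included, so p >= 1/(n_perms + 1). When the restricted
#' permutation group of a term is small (<= \code{enumerate_limit}) the
#' exact p over the full enumeration is returned instead.
#'
#' @param d n x n distance matrix (or \code{dist}) of pairwise Procrustes
#'   (or form-space) distances, ordered as the design rows.
#' @param design data.frame with columns \code{subject_id}, \code{stage} and
#'   optionally \code{group}.
#' @param scheme a \code{\link{permutation_scheme}}; by default one is built
#'   from the design with \code{n_perms} and \code{seed}.
#' @param n_perms,seed convenience arguments used when \code{scheme} is NULL.
#' @param terms model terms in fitting order; defaults to
#'   \code{stage + group + stage:group}, dropping group terms when the
#'   design has fewer than two groups.
#' @return A \code{data.frame} of class \code{permanova_table} with one row
#'   per term plus Residual and Total rows; columns \code{term}, \code{df},
#'   \code{SS}, \code{pseudo_F}, \code{partial_R2}, \code{p}. Attributes
#'   record the permutation counts and whether each term was enumerated.
#' @export
permanova <- function(d, design, scheme = NULL, n_perms = 10000L, seed = 1L,
                      terms = NULL) {
  design <- as.data.frame(design)
  stage <- droplevels(as.factor(design$stage))
  group <- if (!is.null(design$group)) droplevels(as.factor(design$group)) else factor(rep("all", nrow(design)))
  blocks <- as.character(design$subject_id)
  n <- length(blocks)
  d <- as.matrix(d)
  if (nrow(d) != n) stop("distance matrix and design sizes differ")
  if (is.null(scheme)) scheme <- permutation_scheme(blocks, n_perms, seed)

  if (is.null(terms)) {
    terms <- "stage"
    if (nlevels(group) > 1L) terms <- c("stage", "group", "stage:group")
  }

  G <- gower_center(d)
  total <- sum(diag(G))
  if (total <= 1e-12 * n)
    stop("undefined pseudo-F: response has zero total sum of squares")

  obs <- seq_ss(G, stage, group, terms)
  F_obs <- (obs$ss / obs$df) / (obs$ss_res / obs$df_res)

  bi <- block_index(blocks)
  if (any(lengths(bi) == 1L) && any(scheme$rules[terms] == "within_subject"))
    message(sum(lengths(bi) == 1L),
            " subject(s) with a single observation contribute no within-subject shuffling")
  subjects <- names(bi)
  n_subj <- length(subjects)

  set.seed(scheme$seed)
  ftol <- 1e-8 * pmax(abs(F_obs), 1)
  p <- setNames(rep(NA_real_, length(terms)), terms)
  enumerated <- setNames(logical(length(terms)), terms)
  n_used <- setNames(integer(length(terms)), terms)

  need_within <- terms[scheme$rules[terms] == "within_subject" |
                         is.na(scheme$rules[terms])]
  need_between <- terms[!is.na(scheme$rules[terms]) &
                          scheme$rules[terms] == "between_subject"]

  if (length(need_within)) {
    gsize <- within_group_size(bi)
    if (gsize <= scheme$enumerate_limit) {
      pis <- enumerate_within(bi, n)
      Fs <- vapply(pis, function(pi) {
        dec <- seq_ss(G[pi, pi], stage, group, terms)
        (dec$ss[need_within] / dec$df[need_within]) / (dec$ss_res / dec$df_res)
      }, numeric(length(need_within)))
      Fs <- matrix(Fs, nrow = length(need_within))
      for (j in seq_along(need_within)) {
        tm <- need_within[j]
        p[tm] <- mean(Fs[j, ] >= F_obs[tm] - ftol[tm])
        enumerated[tm] <- TRUE
        n_used[tm] <- length(pis)
      }
    } else {
      B <- scheme$n_perms
      cnt <- setNames(numeric(length(need_within)), need_within)
      for (b in seq_len(B)) {
        pi <- sample_within(bi, n)
        dec <- seq_ss(G[pi, pi], stage, group, terms)
        Fb <- (dec$ss[need_within] / dec$df[need_within]) / (dec$ss_res / dec$df_res)
        cnt <- cnt + (Fb >= F_obs[need_within] - ftol[need_within])
      }
      p[need_within] <- (cnt + 1) / (B + 1)
      n_used[need_within] <- B
    }
  }

  if (length(need_between)) {
    gsize <- factorial(n_subj)
    if (gsize <= scheme$enumerate_limit) {
      sp <- perms_of(n_subj)
      Fs <- vapply(sp, function(sg) {
        g2 <- permute_group_labels(group, blocks, sg, subjects)
        dec <- seq_ss(G, stage, g2, terms)
        (dec$ss[need_between] / dec$df[need_between]) / (dec$ss_res / dec$df_res)
      }, numeric(length(need_between)))
      Fs <- matrix(Fs, nrow = length(need_between))
      for (j in seq_along(need_between)) {
        tm <- need_between[j]
        p[tm] <- mean(Fs[j, ] >= F_obs[tm] - ftol[tm])
        enumerated[tm] <- TRUE
        n_used[tm] <- length(sp)
      }
    } else {
      B <- scheme$n_perms
      cnt <- setNames(numeric(length(need_between)), need_between)
      for (b in seq_len(B)) {
        g2 <- permute_group_labels(group, blocks, sample.int(n_subj), subjects)
        dec <- seq_ss(G, stage, g2, terms)
        Fb <- (dec$ss[need_between] / dec$df[need_between]) / (dec$ss_res / dec$df_res)
        cnt <- cnt + (Fb >= F_obs[need_between] - ftol[need_between])
      }
      p[need_between] <- (cnt + 1) / (B + 1)
      n_used[need_between] <- B
    }
  }

  r2 <- partial_r2(obs$ss, obs$ss_res)
  tab <- data.frame(term = c(terms, "Residual", "Total"),
                    df = c(obs$df, obs$df_res, obs$df_total),
                    SS = c(obs$ss, obs$ss_res, obs$ss_total),
                    pseudo_F = c(F_obs, NA, NA),
                    partial_R2 = c(r2, NA, NA),
                    p = c(p, NA, NA),
                    row.names = NULL)
  structure(tab, class = c("permanova_table", "data.frame"),
            n_perms = n_used, enumerated = enumerated,
            rules = scheme$rules, seed = scheme$seed)
}

#' @export
print.permanova_table <- function(x, ...) {
  cat("Permutational MANOVA (distance matrix, sequential SS)\n")
  rules <- attr(x, "rules")
  if (!is.null(rules))
    cat("  permutation rules:",
        paste(names(rules), rules, sep = "=", collapse = ", "), "\n")
  print.data.frame(format(as.data.frame(x), digits = 5), row.names = FALSE)
  invisible(x)
}

#' Pairwise Procrustes distance matrix
#'
#' @param shapes k x 3 x n array (or list) of superimposed shape coordinates.
#' @return Symmetric n x n matrix of Euclidean Procrustes distances, zero on
#'   the diagonal.
#' @export
pairwise_distance_matrix <- function(shapes) {
  shapes <- shapes_to_matrix(shapes)
  as.matrix(stats::dist(shapes))
}

# flatten k x 3 x n array (or list of k x 3) into n x 3k row-per-shape matrix
shapes_to_matrix <- function(shapes) {
  if (is.list(shapes)) {
    shapes <- array(unlist(lapply(shapes, as_coord_matrix), use.names = FALSE),
                    dim = c(nrow(shapes[[1L]]), 3L, length(shapes)))
  }
  stopifnot(length(dim(shapes)) == 3L)
  t(matrix(shapes, dim(shapes)[1L] * 3L, dim(shapes)[3L]))
}

#' Post-hoc pairwise stage comparisons
#'
#' For each pair of stages: the Procrustes distance between the two stage
#' mean shapes, the partial R-squared of the stage term, and a
#' within-subject permutation p-value, computed on the subjects observed at
#' both stages.
#'
#' @param shapes k x 3 x n array of superimposed shapes (or forms), ordered
#'   as the design rows.
#' @param design data.frame with \code{subject_id} and \code{stage}.
#' @param n_perms permutations per pair (enumeration kicks in automatically
#'   for small subsets).
#' @param seed permutation seed.
#' @return data.frame of class \code{posthoc_table}: columns \code{pair},
#'   \code{n_subjects}, \code{pd}, \code{partial_R2}, \code{p}.
#' @export
pairwise_posthoc <- function(shapes, design, n_perms = 10000L, seed = 1L) {
  design <- as.data.frame(design)
  stage <- droplevels(as.factor(design$stage))
  Y <- shapes_to_matrix(shapes)
  lv <- levels(stage)
  if (length(lv) < 2L) stop("need at least two stages for pairwise comparisons")
  rows <- list()
  for (i in seq_len(length(lv) - 1L)) for (j in (i + 1L):length(lv)) {
    a <- lv[i]; b <- lv[j]
    sub_a <- design$subject_id[stage == a]
    sub_b <- design$subject_id[stage == b]
    both <- intersect(sub_a, sub_b)
    if (length(both) == 0L) {
      warning("no subjects observed at both ", a, " and ", b, "; pair skipped")
      next
    }
    keep <- design$subject_id %in% both & stage %in% c(a, b)
    ds <- droplevels(data.frame(subject_id = design$subject_id[keep],
                                stage = stage[keep]))
    Yk <- Y[keep, , drop = FALSE]
    pd <- sqrt(sum((colMeans(Yk[ds$stage == a, , drop = FALSE]) -
                      colMeans(Yk[ds$stage == b, , drop = FALSE]))^2))
    dmat <- as.matrix(stats::dist(Yk))
    scheme <- permutation_scheme(ds$subject_id, n_perms, seed,
                                 rules = c(stage = "within_subject"))
    tab <- permanova(dmat, ds, scheme, terms = "stage")
    rows[[paste(a, b, sep = "-")]] <-
      data.frame(pair = paste(a, b, sep = "-"), n_subjects = length(both),
                 pd = pd, partial_R2 = tab$partial_R2[1L], p = tab$p[1L])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' Procrustes variance (morphological disparity)
#'
#' Mean squared Procrustes distance of group members from their group mean
#' shape, with the 1/n convention.
#'
#' @param shapes k x 3 x n array of superimposed shape (or form) coordinates.
#' @param groups factor of group labels, one per shape.
#' @return Named numeric vector of per-group Procrustes variances.
#' @export
procrustes_variance <- function(shapes, groups) {
  Y <- shapes_to_matrix(shapes)
  groups <- as.factor(groups)   # declared levels kept: an empty group errors
  if (length(groups) != nrow(Y)) stop("groups length must match shape count")
  if (any(table(groups) == 0L)) stop("empty group")
  vapply(levels(groups), function(g) {
    Yg <- Y[groups == g, , drop = FALSE]
    mu <- colMeans(Yg)
    mean(rowSums((Yg - rep(mu, each = nrow(Yg)))^2))
  }, 0)
}

#' Permutation test for differences in Procrustes variance
#'
#' For every pair of groups, the difference in Procrustes variance and a
#' permutation p-value obtained by shuffling the group-mean-centered
#' residual vectors among groups (equivalently, their squared norms) and
#' recomputing the absolute variance difference.
#'
#' @param shapes k x 3 x n array of superimposed coordinates.
#' @param groups factor of group labels.
#' @param n_perms number of permutations.
#' @param seed permutation seed.
#' @return Object of class \code{disparity_result}: \code{variances} (named
#'   per-group PV) and \code{table} (pair, delta_var signed as a - b,
#'   p from the two-sided test on |delta|).
#' @export
disparity_test <- function(shapes, groups, n_perms = 10000L, seed = 1L) {
  Y <- shapes_to_matrix(shapes)
  groups <- droplevels(as.factor(groups))
  pv <- procrustes_variance(shapes, groups)
  lv <- levels(groups)
  if (length(lv) < 2L) stop("need at least two groups")
  # squared norms of group-mean-centered residuals are sufficient for PV
  r2 <- numeric(nrow(Y))
  for (g in lv) {
    sel <- groups == g
    mu <- colMeans(Y[sel, , drop = FALSE])
    r2[sel] <- rowSums((Y[sel, , drop = FALSE] - rep(mu, each = sum(sel)))^2)
  }
  gi <- as.integer(groups)
  ng <- tabulate(gi)
  singletons <- lv[ng == 1L]
  if (length(singletons))
    warning("group(s) of size 1 (", paste(singletons, collapse = ", "),
            "): variance defined but pairwise test skipped")

  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  set.seed(seed)
  perm_pv <- matrix(NA_real_, n_perms, length(lv), dimnames = list(NULL, lv))
  for (b in seq_len(n_perms)) {
    rp <- r2[sample.int(length(r2))]
    perm_pv[b, ] <- vapply(seq_along(lv), function(g) mean(rp[gi == g]), 0)
  }
  rows <- lapply(pairs, function(pr) {
    a <- pr[1L]; b <- pr[2L]
    delta <- pv[a] - pv[b]
    if (a %in% singletons || b %in% singletons)
      return(data.frame(pair = paste(a, b, sep = "-"), delta_var = delta, p = NA_real_))
    cnt <- sum(abs(perm_pv[, a] - perm_pv[, b]) >= abs(delta) - 1e-12)
    data.frame(pair = paste(a, b, sep = "-"), delta_var = delta,
               p = (cnt + 1) / (n_perms + 1))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(variances = pv, table = tab), class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("Procrustes variance (morphological disparity)\n")
  print(round(x$variances, 8))
  cat("pairwise differences:\n")
  print.data.frame(format(x$table, digits = 5), row.names = FALSE)
  invisible(x)
}
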