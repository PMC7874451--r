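# Independent oracles and fixture builders, deliberately coded on different
# paths than the package internals.

random_config <- function(k, scale = 10) {
  matrix(rnorm(k * 3, sd = scale), k, 3)
}

rotation_about_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

unit_center <- function(x) {
  x <- x - matrix(colMeans(x), nrow(x), 3, byrow = TRUE)
  x / sqrt(sum(x^2))
}

# Brute-force pairwise (ordinary Procrustes) superimposition: coarse Euler
# grid followed by local refinement; returns the minimal Euclidean distance
# between the unit-size centered shapes.
opa_distance_oracle <- function(a, b, grid_deg = 20) {
  A <- unit_center(a); B <- unit_center(b)
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sum((A - B %*% R)^2)
  }
  gr <- seq(0, 2 * pi, by = grid_deg * pi / 180)
  grb <- seq(0, pi, by = grid_deg * pi / 180)
  cand <- expand.grid(p = gr, q = grb, r = gr)
  vals <- apply(cand, 1, obj)
  best <- Inf
  for (i in order(vals)[1:15]) {   # local refinement from the best grid cells
    ref <- optim(as.numeric(cand[i, ]), obj, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 1000))
    ref <- optim(ref$par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 2000))
    best <- min(best, ref$value)
  }
  sqrt(best)
}

# Dense hand-built thin-plate-spline solve (kernel U(r) = r), written as
# explicit loops, independent of the package's vectorized solver.
tps_oracle <- function(src, dst, queries) {
  n <- nrow(src)
  L <- matrix(0, n + 4, n + 4)
  for (i in seq_len(n)) for (j in seq_len(n))
    L[i, j] <- sqrt(sum((src[i, ] - src[j, ])^2))
  for (i in seq_len(n)) {
    L[i, n + 1] <- L[n + 1, i] <- 1
    L[i, n + 2:4] <- src[i, ]
    L[n + 2:4, i] <- src[i, ]
  }
  rhs <- rbind(dst, matrix(0, 4, 3))
  coefs <- qr.solve(L, rhs)
  out <- matrix(0, nrow(queries), 3)
  for (q in seq_len(nrow(queries))) {
    acc <- coefs[n + 1, ] + as.numeric(queries[q, ] %*% coefs[n + 2:4, ])
    for (i in seq_len(n))
      acc <- acc + coefs[i, ] * sqrt(sum((queries[q, ] - src[i, ])^2))
    out[q, ] <- acc
  }
  out
}

# Sequential multivariate sums of squares via explicit lm() refits
lm_seq_ss_oracle <- function(Y, stage, group = NULL) {
  sse <- function(fml, dat) sum(residuals(lm(fml, data = dat))^2)
  dat <- data.frame(stage = stage)
  Y <- as.matrix(Y)
  if (is.null(group)) {
    s0 <- sse(Y ~ 1, dat)
    s1 <- sse(Y ~ stage, dat)
    list(ss = c(stage = s0 - s1), ss_res = s1,
         df = c(stage = nlevels(droplevels(as.factor(stage))) - 1))
  } else {
    dat$group <- group
    s0 <- sse(Y ~ 1, dat)
    s1 <- sse(Y ~ stage, dat)
    s2 <- sse(Y ~ stage + group, dat)
    s3 <- sse(Y ~ stage * group, dat)
    list(ss = c(stage = s0 - s1, group = s1 - s2, `stage:group` = s2 - s3),
         ss_res = s3)
  }
}

# Exhaustive within-subject permutation p for 2-stage data via lm oracle
exact_perm_oracle <- function(Y, subject, stage) {
  n_sub <- length(unique(subject))
  stopifnot(nlevels(droplevels(as.factor(stage))) == 2)
  f_of <- function(st) {
    o <- lm_seq_ss_oracle(Y, droplevels(as.factor(st)))
    df_res <- nrow(Y) - 2
    (o$ss[["stage"]] / 1) / (o$ss_res / df_res)
  }
  F_obs <- f_of(stage)
  flips <- expand.grid(rep(list(c(FALSE, TRUE)), n_sub))
  subjects <- unique(subject)
  Fs <- apply(flips, 1, function(fl) {
    st <- as.character(stage)
    for (s in seq_len(n_sub)) {
      if (fl[s]) {
        ix <- which(subject == subjects[s])
        st[ix] <- rev(st[ix])
      }
    }
    f_of(st)
  })
  mean(Fs >= F_obs - 1e-8 * max(1, abs(F_obs)))
}

# small longitudinal dataset in shape-coordinate space (already superimposed)
toy_longitudinal <- function(n_sub, stages = c("T0", "T1"), k = 6,
                             stage_effect = 0.5, subject_sd = 1, noise_sd = 0.3) {
  ns <- length(stages)
  design <- data.frame(subject_id = rep(sprintf("S%02d", 1:n_sub), each = ns),
                       stage = rep(stages, n_sub))
  Y <- matrix(0, n_sub * ns, 3 * k)
  effects <- outer(seq_len(ns) - 1, rnorm(3 * k), `*`) * stage_effect
  r <- 0
  for (s in 1:n_sub) {
    subj <- rnorm(3 * k, sd = subject_sd)
    for (t in 1:ns) {
      r <- r + 1
      Y[r, ] <- subj + effects[t, ] + rnorm(3 * k, sd = noise_sd)
    }
  }
  list(design = design, Y = Y,
       shapes = array(t(Y), dim = c(k, 3, nrow(Y))))
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
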