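# Independent reference computations used to cross-check the package.
# Each oracle is written as a direct transcription of the textbook
# definition (loops, enumeration, closed forms) and shares no code with
# the implementation it checks.

uniform_suv <- function(value, dims = c(16, 16, 16), spacing = 2) {
  pet_volume(array(value, dim = dims), spacing = spacing, units = "SUV")
}

# exhaustive SUV triplet: plain loops over the grid
bf_triplet <- function(suv, mask, peak_diameter_mm) {
  d <- dim(suv$values)
  sp <- suv$spacing
  vals <- c()
  centers <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (mask[i, j, k]) {
      vals <- c(vals, suv$values[i, j, k])
      centers <- rbind(centers, c(i, j, k))
    }
  }
  r <- peak_diameter_mm / 2
  best <- -Inf
  for (c_i in seq_len(nrow(centers))) {
    cw <- (centers[c_i, ] - 1) * sp
    member <- c()
    fits <- TRUE
    reach <- ceiling(r / sp)
    for (dz in -reach[3]:reach[3]) for (dy in -reach[2]:reach[2])
      for (dx in -reach[1]:reach[1]) {
        if (sqrt(sum((c(dx, dy, dz) * sp)^2)) <= r) {
          p <- centers[c_i, ] + c(dx, dy, dz)
          if (any(p < 1) || any(p > d)) { fits <- FALSE
          } else member <- c(member, suv$values[p[1], p[2], p[3]])
        }
      }
    if (fits) best <- max(best, mean(member))
  }
  list(suv_max = max(vals), suv_mean = mean(vals), suv_peak = best,
       n_voxels = length(vals))
}

bf_min_distance <- function(mask_a, mask_b, spacing) {
  a <- which(mask_a, arr.ind = TRUE)
  b <- which(mask_b, arr.ind = TRUE)
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    best <- min(best, sqrt(sum(((a[i, ] - b[j, ]) * spacing)^2)))
  }
  best
}

# one-sample t: closed form plus the t distribution
bf_t_test <- function(d) {
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(stat = t, p = 2 * pt(-abs(t), n - 1))
}

# Pearson r and its t-based two-sided p
bf_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Kendall tau-b by O(n^2) concordant/discordant pair counting
bf_tau_b <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tie_x <- 0; tie_y <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    # a pair tied in a variable is discounted from that variable's
    # pair total; ties in both discount from both
    if (a == 0) tie_x <- tie_x + 1
    if (b == 0) tie_y <- tie_y + 1
    if (a != 0 && b != 0) {
      if (a == b) conc <- conc + 1 else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# exact signed-rank p by enumerating all 2^n sign assignments
# (requires no zeros and no tied absolute values)
bf_signrank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# exact two-sided Kendall p by enumerating all n! pairings
bf_kendall_exact_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  t_obs <- bf_tau_b(x, y)
  taus <- vapply(perms(seq_along(y)), function(p) bf_tau_b(x, y[p]),
                 numeric(1))
  mean(abs(taus) >= abs(t_obs) - 1e-12)
}

# Shapiro-Wilk (W, p) computed with scipy.stats.shapiro 1.17.1 on these
# exact vectors; R and scipy implement the same Royston AS R94 algorithm
SHAPIRO_ORACLE <- list(
  list(x = c(2.685479, 1.717651, 2.181564, 2.316431, 2.202134, 1.946938,
             2.755891, 1.95266),
       W = 0.940186714331, p = 0.612918376591),
  list(x = c(3.009212, 1.971762, 2.652579, 3.146408, 1.930036, 2.364945,
             2.088534, 1.094958, 1.79951, 2.110387, 1.881562, 1.686037),
       W = 0.951062889887, p = 0.652573160771),
  list(x = c(1.953359, 1.838659, 2.523064, 2.426396, 1.665412, 2.281331,
             2.175012, 2.81465, 2.401743, 1.263604, 2.378533, 2.096066,
             1.94363, 2.384647, 1.606981, 1.582209, 2.660819, 1.97414,
             2.489188, 2.366854, 2.602269, 2.228869),
       W = 0.961588635971, p = 0.522049375942))

# printed reference summary tables shipped with the package
reference_tables <- function() {
  read.csv(system.file("extdata", "reference_repeatability_tables.csv",
                       package = "suvrepeat"),
           stringsAsFactors = FALSE)
}

# a small measurement cohort most tests can share
tiny_cohort <- function(seed = 11, n_subjects = 12) {
  generate_cohort(cohort_config(n_subjects = n_subjects, seed = seed))
}
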