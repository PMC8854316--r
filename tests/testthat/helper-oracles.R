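# Independent numerical oracles used across the test files. These deliberately
# avoid the code paths they check: fixed-grid composite quadrature instead of
# adaptive quadrature, an Euler-integral hypergeometric instead of the power
# series, a parametric linear solve instead of orientation tests.

# composite-trapezoid integral on a fixed grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# dense-grid oracle for the JZS t Bayes factor
oracle_bf_ttest <- function(t, n1, n2, cauchy_scale = 1 / sqrt(2),
                            effective_n = "df", npts = 200001) {
  nu <- n1 + n2 - 2
  neff <- if (effective_n == "df") nu + 1 else n1 * n2 / (n1 + n2)
  d <- seq(-25, 25, length.out = npts)
  y <- suppressWarnings(dt(t, nu, ncp = d * sqrt(neff))) *
    dcauchy(d, 0, cauchy_scale)
  trapz(d, y) / dt(t, nu)
}

# dense-grid oracle for the Zellner-Siow correlation Bayes factor;
# integrates over u = g / (1 + g) in (0, 1)
oracle_bf_pearson_jzs <- function(r, n, npts = 200001) {
  u <- seq(1e-9, 1 - 1e-9, length.out = npts)
  g <- u / (1 - u)
  logy <- ((n - 2) / 2) * log1p(g) - ((n - 1) / 2) * log1p((1 - r^2) * g) +
    0.5 * log(n / 2) - lgamma(0.5) - 1.5 * log(g) - n / (2 * g) -
    2 * log1p(-u)
  trapz(u, exp(logy))
}

# Gauss 2F1 via its Euler integral (c > b > 0), substitution t = s^2 to tame
# the endpoint singularity at b = 1/2
oracle_hyp2f1 <- function(a, b, cc, z) {
  f <- function(s) 2 * s^(2 * b - 1) * (1 - s^2)^(cc - b - 1) * (1 - z * s^2)^(-a)
  integrate(f, 0, 1, rel.tol = 1e-12)$value / beta(b, cc - b)
}

oracle_dr_given_rho <- function(r, rho, n) {
  lc <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
    ((n - 4) / 2) * log1p(-r^2) - 0.5 * log(2 * pi) - lgamma(n - 0.5) -
    (n - 1.5) * log1p(-rho * r)
  exp(lc) * oracle_hyp2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
}

# dense-grid oracle for the stretched-beta correlation Bayes factor
oracle_bf_pearson_sb <- function(r, n, width = 1, npts = 4001) {
  a <- 1 / width
  rho <- seq(-1 + 1e-8, 1 - 1e-8, length.out = npts)
  y <- vapply(rho, function(p) oracle_dr_given_rho(r, p, n), numeric(1)) *
    dbeta((rho + 1) / 2, a, a) / 2
  trapz(rho, y) / oracle_dr_given_rho(r, 0, n)
}

# parametric-solve segment intersection oracle: solve a + s(b-a) = c + t(d-c)
oracle_segments_intersect <- function(s1, s2) {
  a <- s1[1:2]; b <- s1[3:4]; c <- s2[1:2]; d <- s2[3:4]
  M <- cbind(b - a, -(d - c))
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (abs(det) > 1e-14) {
    st <- solve(M, c - a)
    return(all(st >= 0 & st <= 1))
  }
  # parallel; intersect only if collinear and the parameter ranges overlap
  u <- b - a
  w <- c - a
  if (abs(u[1] * w[2] - u[2] * w[1]) > 1e-12) return(FALSE)
  L2 <- sum(u^2)
  tc <- sum((c - a) * u) / L2
  td <- sum((d - a) * u) / L2
  max(min(tc, td), 0) <= min(max(tc, td), 1)
}

# dense point-sampling: minimum distance between sampled points of s1 and s2
oracle_sampled_min_distance <- function(s1, s2, k = 60) {
  t <- seq(0, 1, length.out = k)
  p1x <- s1[1] + t * (s1[3] - s1[1]); p1y <- s1[2] + t * (s1[4] - s1[2])
  p2x <- s2[1] + t * (s2[3] - s2[1]); p2y <- s2[2] + t * (s2[4] - s2[2])
  min(sqrt(outer(p1x, p2x, "-")^2 + outer(p1y, p2y, "-")^2))
}

# hand-rolled within-subject ANOVA cross-check via stats::aov error strata
oracle_rm_anova <- function(data) {
  data$subject <- factor(data$subject)
  data$A <- factor(data$A)
  data$B <- factor(data$B)
  fit <- stats::aov(value ~ A * B + Error(subject / (A * B)), data = data)
  s <- summary(fit)
  get_f <- function(stratum, row) {
    tab <- s[[stratum]][[1]]
    tab[row, "F value"]
  }
  c(A = get_f("Error: subject:A", "A"),
    B = get_f("Error: subject:B", "B"),
    AB = get_f("Error: subject:A:B", "A:B"))
}

# stationary-observer QUEST block: returns final state and responses
run_quest_block <- function(pse_true, sigma_true, ref, n_trials = 180,
                            lapse_true = 0.02,
                            pcfg = perturbation_config()) {
  st <- quest_init(ref, 0.4 * ref, 0.25 * ref, lapse = 0.02)
  chose <- logical(n_trials)
  probes <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    x <- next_probe(st, pcfg)
    p <- lapse_true / 2 + (1 - lapse_true) * pnorm((x - pse_true) / sigma_true)
    y <- runif(1) < p
    st <- quest_update(st, x, y)
    chose[i] <- y
    probes[i] <- x
  }
  list(state = st, chose = chose, probes = probes)
}
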