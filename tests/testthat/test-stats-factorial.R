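test_that("balanced 2x2 ANOVA matches hand-computed sums of squares", {
  set.seed(101)
  cells <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
  mu <- c(10, 12, 20, 26)
  d <- do.call(rbind, lapply(1:4, function(i)
    data.frame(A = cells$A[i], B = cells$B[i],
               y = mu[i] + rnorm(2, 0, 1))))
  at <- factorial_anova(d, "y", c("A", "B"))
  # independent hand arithmetic from cell means (n = 2 per cell)
  cm <- tapply(d$y, list(d$A, d$B), mean)
  gm <- mean(d$y)
  ssA <- 4 * sum((rowMeans(cm) - gm)^2)
  ssB <- 4 * sum((colMeans(cm) - gm)^2)
  ssAB <- 2 * sum((cm - outer(rowMeans(cm), colMeans(cm), "+") + gm)^2)
  ssE <- sum((d$y - cm[cbind(d$A, d$B)])^2)
  expect_equal(at$SS[at$effect == "A"], ssA, tolerance = 1e-8)
  expect_equal(at$SS[at$effect == "B"], ssB, tolerance = 1e-8)
  expect_equal(at$SS[at$effect == "A:B"], ssAB, tolerance = 1e-8)
  expect_equal(at$SS[at$effect == "Residuals"], ssE, tolerance = 1e-8)
  # the partition is exact: total SS = sum of effect SS
  expect_equal(sum(at$SS), sum((d$y - gm)^2), tolerance = 1e-8)
  expect_equal(at$F[at$effect == "A"], (ssA / 1) / (ssE / 4),
               tolerance = 1e-8)
})

test_that("additive zero-noise design has exactly zero interaction SS", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:2)
  d$y <- ifelse(d$A == "a2", 5, 0) + ifelse(d$B == "b2", 3, 0)
  at <- suppressWarnings(factorial_anova(d, "y", c("A", "B")))
  expect_equal(at$SS[at$effect == "A:B"], 0, tolerance = 1e-12)
})

test_that("single-factor F equals the squared two-sample t statistic", {
  set.seed(5)
  d <- data.frame(g = rep(c("x", "y"), each = 6),
                  y = c(rnorm(6, 10), rnorm(6, 12)))
  at <- factorial_anova(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(at$F[at$effect == "g"], unname(tt$statistic)^2)
})

test_that("empty design cells are reported by name", {
  d <- data.frame(A = c("a1", "a1", "a2", "a2"),
                  B = c("b1", "b2", "b1", "b1"),
                  y = rnorm(4))
  expect_error(factorial_anova(d, "y", c("A", "B")), "a2.b2")
})

test_that("unbalanced designs fall back to Type II with a warning", {
  set.seed(8)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  d$y <- rnorm(nrow(d), ifelse(d$A == "a2", 2, 0))
  d <- d[-1, ]  # drop one replicate
  expect_warning(at <- factorial_anova(d, "y", c("A", "B")), "Type II")
  expect_false(attr(at, "balanced"))
  expect_true(all(is.finite(at$F[at$effect != "Residuals"])))
})

test_that("widely separated pairs get distinct Duncan letters", {
  set.seed(2)
  v <- c(rnorm(4, 10, 0.1), rnorm(4, 25, 0.1))
  g <- rep(c("lo", "hi"), each = 4)
  res <- duncan_test(v, g)
  expect_equal(sort(res$letters), c("a", "b"))
})

test_that("identical groups share one Duncan letter", {
  set.seed(3)
  v <- rnorm(12, 10, 1)
  g <- rep(c("p", "q", "r"), each = 4)
  res <- duncan_test(v, g)
  expect_equal(unique(res$letters), "a")
})

test_that("unequal group sizes use the harmonic mean n with warning", {
  set.seed(4)
  v <- c(rnorm(4, 0), rnorm(6, 10))
  g <- rep(c("u", "v"), c(4, 6))
  expect_warning(res <- duncan_test(v, g), "harmonic")
  expect_equal(sort(res$letters), c("a", "b"))
})

test_that("Duncan grouping equals the stepwise range-test oracle", {
  set.seed(606)
  n_agree <- 0
  n_cases <- 200
  for (case in seq_len(n_cases)) {
    k <- sample(2:6, 1)
    n <- sample(3:6, 1)
    spread <- runif(1, 0, 6)
    mus <- runif(k, 0, spread)
    v <- as.vector(vapply(mus, function(m) rnorm(n, m, 1), numeric(n)))
    g <- rep(paste0("g", seq_len(k)), each = n)
    res <- duncan_test(v, g)
    orc <- duncan_oracle(v, g)
    rel <- letters_to_relation(res, orc$order)
    if (identical(unname(rel), unname(orc$nonsig))) n_agree <- n_agree + 1
  }
  expect_equal(n_agree, n_cases)
})

test_that("simple regression returns exact fits and orthogonal nulls", {
  x <- 1:10
  r <- suppressWarnings(simple_regression(x, 2 * x))  # perfect fit warns
  expect_equal(r$slope, 2)
  expect_equal(r$r2, 1)
  # constructed orthogonal sample: y has no linear association with x
  x2 <- c(-2, -1, 0, 1, 2)
  y2 <- c(4, 1, 0, 1, 4)  # symmetric, cov(x, y) = 0
  r2 <- simple_regression(x2, y2)
  expect_equal(r2$slope, 0)
  expect_equal(r2$r2, 0)
  expect_error(simple_regression(rep(1, 5), rnorm(5)), "variance")
})

test_that("generator-targeted association strength is recovered", {
  set.seed(77)
  n <- 60
  act <- runif(n, 0.3, 0.9)
  # choose noise so that the population R2 is 0.5
  slope <- 30
  sd_sig <- slope * stats::sd(act)
  y <- 10 + slope * act + rnorm(n, 0, sd_sig)
  r <- simple_regression(act, y)
  expect_lt(abs(r$r2 - 0.5), 0.1)
  expect_lt(r$p, 0.05)
})
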