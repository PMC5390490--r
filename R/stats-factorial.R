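# Factorial ANOVA, Duncan's multiple range test and simple regressions.

#' Fixed-effects factorial ANOVA
#'
#' Fits the full factorial fixed-effects model (all interactions) for a
#' response over the given factor columns. Balanced designs use the exact
#' sequential sum-of-squares partition (which is order-invariant there);
#' unbalanced designs (replicate loss) fall back to Type II sums of
#' squares via `car::Anova` with a warning.
#'
#' @param data Data frame of replicate-level observations.
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (each with >= 2
#'   levels; every cell of the cross needs >= 1 observation, and >= 2 for
#'   a residual-based test).
#' @return Data frame with one row per effect plus `Residuals`: `Df`,
#'   `SS`, `MS`, `F`, `p`.
#' @export
factorial_anova <- function(data, response, factors) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)))
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2)
      stop("factor ", f, " has fewer than 2 levels")
  }
  cells <- interaction(data[factors], drop = FALSE)
  counts <- table(cells)
  if (any(counts == 0))
    stop("empty design cell(s): ",
         paste(utils::head(names(counts)[counts == 0], 5), collapse = ", "))
  balanced <- length(unique(counts)) == 1
  fml <- stats::as.formula(
    paste(response, "~", paste(factors, collapse = " * ")))
  fit <- lm(fml, data = data)
  if (balanced) {
    at <- anova(fit)
  } else {
    if (!requireNamespace("car", quietly = TRUE))
      stop("unbalanced design needs the car package for Type II SS")
    warning("unbalanced design: using Type II sums of squares")
    a2 <- car::Anova(fit, type = 2)
    at <- a2[, c("Df", "Sum Sq", "F value", "Pr(>F)")]
    at$`Mean Sq` <- at$`Sum Sq` / at$Df
    at <- at[, c("Df", "Sum Sq", "Mean Sq", "F value", "Pr(>F)")]
  }
  out <- data.frame(effect = rownames(at), Df = at$Df, SS = at$`Sum Sq`,
                    MS = at$`Sum Sq` / at$Df, F = at$`F value`,
                    p = at$`Pr(>F)`, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "balanced") <- balanced
  attr(out, "fit") <- fit
  out
}

# Duncan's least significant range for span p at protection level
# alpha_p = 1 - (1 - alpha)^(p - 1), using the studentized range quantile.
duncan_lsr <- function(p, df, ms, n, alpha) {
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  qtukey(1 - alpha_p, p, df) * sqrt(ms / n)
}

#' Duncan's multiple range test
#'
#' Ranks the group means and compares every pair spanning `p` ordered
#' means against Duncan's least significant range
#' \eqn{LSR_p = q(\alpha_p, p, df)\sqrt{MS_{res}/n}} with the protection
#' level \eqn{\alpha_p = 1 - (1-\alpha)^{p-1}}, applying the standard
#' containment rule: a range found non-significant protects all ranges
#' inside it. Letters are assigned by the usual sweep over maximal
#' non-significant spans. With unequal group sizes the harmonic mean n is
#' used, with a warning.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param alpha Significance level (default 0.05).
#' @param ms_res,df_res Residual mean square and df; computed from the
#'   one-way ANOVA of `values ~ groups` when omitted (supply the factorial
#'   model's residuals to test within a wider design).
#' @return Data frame (class `duncan_grouping`): per group the mean, n and
#'   letter set; groups sharing a letter are not significantly different.
#' @export
duncan_test <- function(values, groups, alpha = 0.05,
                        ms_res = NULL, df_res = NULL) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  n_g <- tapply(values, groups, length)
  if (any(n_g < 2) && is.null(ms_res))
    stop("every group needs n >= 2 (or supply ms_res/df_res)")
  if (is.null(ms_res) || is.null(df_res)) {
    fit <- lm(values ~ groups)
    ms_res <- sum(resid(fit)^2) / fit$df.residual
    df_res <- fit$df.residual
  }
  if (length(unique(n_g)) > 1) {
    warning("unequal group sizes: using harmonic mean n")
    n <- length(n_g) / sum(1 / n_g)
  } else n <- n_g[[1]]
  means <- tapply(values, groups, mean)
  ord <- order(means)
  m <- means[ord]
  k <- length(m)
  nonsig <- matrix(FALSE, k, k)
  diag(nonsig) <- TRUE
  if (k >= 2) {
    # widest spans first; containment protects inner ranges
    for (s in seq(k, 2)) {
      lsr <- duncan_lsr(s, df_res, ms_res, n, alpha)
      for (i in seq_len(k - s + 1)) {
        j <- i + s - 1
        covered <- FALSE
        if (s < k) {
          for (a in seq_len(i)) {
            bb <- seq(j, k)
            if (any(nonsig[a, bb] & (bb - a + 1) > s)) {
              covered <- TRUE
              break
            }
          }
        }
        nonsig[i, j] <- covered || (m[j] - m[i] <= lsr)
        nonsig[j, i] <- nonsig[i, j]
      }
    }
  }
  letters_sorted <- assign_letters(nonsig)
  out <- data.frame(group = names(m), mean = as.numeric(m),
                    n = as.numeric(n_g[ord]),
                    letters = letters_sorted, stringsAsFactors = FALSE)
  out <- out[match(levels(groups), out$group), ]
  rownames(out) <- NULL
  attr(out, "ms_res") <- ms_res
  attr(out, "df_res") <- df_res
  attr(out, "alpha") <- alpha
  class(out) <- c("duncan_grouping", "data.frame")
  out
}

# letters from a symmetric non-significance matrix over sorted means:
# one letter per maximal interval [i, j] with all pairs non-significant
assign_letters <- function(nonsig) {
  k <- nrow(nonsig)
  # rightmost extension of an all-non-significant interval starting at i
  r <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(nonsig[i:(j + 1), i:(j + 1)])) j <- j + 1
    r[i] <- j
  }
  # an interval is maximal unless an earlier start reaches at least as far
  starts <- which(r > cummax(c(0L, r[-k])) | seq_len(k) == 1L)
  starts <- starts[!duplicated(r[starts])]
  lab <- vapply(seq_along(starts), make_letter, character(1))
  out <- character(k)
  for (i in seq_len(k)) {
    mem <- starts <= i & i <= r[starts]
    out[i] <- paste(lab[mem], collapse = "")
  }
  out
}

make_letter <- function(i) {
  if (i <= 26) letters[i] else paste0(letters[(i - 1) %/% 26], letters[(i - 1) %% 26 + 1])
}

#' @export
print.duncan_grouping <- function(x, ...) {
  cat("Duncan's multiple range test (alpha =", attr(x, "alpha"), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Ordinary least-squares regression summary
#'
#' Simple y ~ x regression with slope, intercept, R2 and the slope's
#' t-test p-value, the form used for the trait-trait relationships
#' (assimilation vs activation state, activation state vs electron
#' transport, activase/Rubisco ratio vs chloroplast CO2).
#'
#' @param x,y Numeric vectors (n >= 3; x must vary).
#' @return List with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
simple_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (var(x) == 0) stop("x has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = coef(fit)[["x"]], intercept = coef(fit)[[1]],
       r2 = sm$r.squared, p = sm$coefficients["x", "Pr(>|t|)"],
       n = length(x))
}
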