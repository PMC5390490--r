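# Shared fixtures and independent oracles for the test suite.

# A minimal well-formed leaf-record table built in code.
make_leaf_df <- function(n = 3, species = "rice") {
  data.frame(
    species = species, irrigation = "WW", temperature = "control25",
    replicate_id = paste0("r", seq_len(n)),
    AN = seq(15, 15 + n - 1), gs = 0.3, Ci = 280, Ca = 400, PPFD = 1500,
    Tleaf = 25, Rdark = 1.5, Fs = 0.4, Fm_prime = 0.7, alpha = 0.87,
    beta = 0.5, stringsAsFactors = FALSE)
}

# Independent stepwise Duncan oracle: recursive textbook procedure over
# ordered means. Returns the symmetric "not significantly different"
# matrix in mean-sorted order, plus the sorted group names.
duncan_oracle <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  fit <- stats::lm(values ~ groups)
  ms <- sum(stats::resid(fit)^2) / fit$df.residual
  dfr <- fit$df.residual
  n_g <- tapply(values, groups, length)
  n <- if (length(unique(n_g)) > 1) length(n_g) / sum(1 / n_g) else n_g[[1]]
  m <- sort(tapply(values, groups, mean))
  k <- length(m)
  nonsig <- diag(k) == 1
  mark <- function(i, j) {
    nonsig[i:j, i:j] <<- TRUE
  }
  test_range <- function(i, j) {
    if (i >= j) return(invisible(NULL))
    if (all(nonsig[i:j, i:j])) return(invisible(NULL))  # protected
    p <- j - i + 1
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    lsr <- stats::qtukey(1 - alpha_p, p, dfr) * sqrt(ms / n)
    if (m[j] - m[i] <= lsr) {
      mark(i, j)
    } else {
      test_range(i, j - 1)
      test_range(i + 1, j)
    }
  }
  test_range(1, k)
  list(nonsig = nonsig, order = names(m))
}

# Pairwise same-letter relation implied by a duncan_test() result, in the
# given group order.
letters_to_relation <- function(grouping, order) {
  g <- grouping[match(order, grouping$group), ]
  k <- nrow(g)
  rel <- diag(k) == 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      li <- strsplit(g$letters[i], "")[[1]]
      lj <- strsplit(g$letters[j], "")[[1]]
      rel[i, j] <- length(intersect(li, lj)) > 0
    }
  }
  rel
}
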