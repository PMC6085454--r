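# Independent oracles used across the suite.  These deliberately use
# different mechanisms from the implementation (PCRE regex, naive window
# scans, exhaustive searches) so that agreement is informative.

# IUPAC consensus matching via PCRE character classes with a lookahead so
# overlapping matches are all reported
iupac_regex_starts <- function(seq, pattern) {
  classes <- c(A = "A", C = "C", G = "G", T = "T",
               R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
               K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
               H = "[ACT]", V = "[ACG]", N = "[ACGTN]")
  # subject N may only match pattern N
  rx <- paste(classes[strsplit(toupper(pattern), "")[[1]]], collapse = "")
  m <- gregexpr(paste0("(?=", rx, ")"), toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

revcomp_chr <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive left-to-right non-overlapping heme-motif counter (character loop,
# shortest spacer first) -- mirrors the definition, not the implementation
heme_count_oracle <- function(protein, spacers = 2) {
  aa <- strsplit(toupper(protein), "")[[1]]
  n <- length(aa)
  count <- 0L
  i <- 1L
  ok_res <- function(x) x %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  while (i <= n) {
    adv <- 1L
    if (identical(aa[i], "C")) {
      for (sp in spacers) {
        j <- i + sp + 1L
        if (j + 1L <= n && identical(aa[j], "C") &&
            identical(aa[j + 1L], "H") &&
            all(vapply(aa[(i + 1L):(j - 1L)], ok_res, logical(1)))) {
          count <- count + 1L
          adv <- sp + 3L
          break
        }
      }
    }
    i <- i + adv
  }
  count
}

# exhaustive two-segment piecewise-linear knot search (same definition as
# the implementation but written independently: grid over knots, closed-form
# lm at each)
breakpoint_oracle <- function(t, y) {
  cand <- t[3:(length(t) - 2)]
  sse <- vapply(cand, function(k) {
    X <- cbind(1, t, pmax(t - k, 0))
    r <- stats::lsfit(X, y, intercept = FALSE)$residuals
    sum(r^2)
  }, numeric(1))
  cand[which.min(sse)]
}

# random feasible phase summary (F >= 4L)
random_phase <- function() {
  L <- stats::runif(1, 0, 5)
  F_ <- 4 * L + stats::runif(1, 0, 40)
  H <- stats::runif(1, 0, 50)
  phase_summary(L, F_, H)
}
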