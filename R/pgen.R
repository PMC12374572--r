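#' Allele frequencies, plain or round-robin
#'
#' Round-robin estimation (the standard for clonal data) removes the
#' inflation caused by large clones: for each locus i, samples are collapsed
#' to MLGs using all loci EXCEPT i, one representative is kept per such MLG
#' (the first in sample order), and allele frequencies at locus i are counted
#' over those representatives' two alleles and normalized. Plain mode counts
#' over all samples.
#'
#' @param ss A `sample_set` (strict mode).
#' @param mode `"round_robin"` (default) or `"plain"`. A single-locus panel
#'   cannot be round-robined and falls back to plain with a warning.
#' @return An object of class `allele_freq_table`: a named list (one element
#'   per locus) of named numeric vectors (allele size -> frequency, each
#'   summing to 1), with an `estimation_mode` attribute.
#' @export
allele_freqs <- function(ss, mode = c("round_robin", "plain")) {
  mode <- match.arg(mode)
  loci <- ss$panel$loci
  if (mode == "round_robin" && length(loci) == 1L) {
    warning("round-robin is undefined for a single locus; using plain ",
            "frequencies")
    mode <- "plain"
  }
  out <- vector("list", length(loci))
  names(out) <- loci
  for (i in seq_along(loci)) {
    if (mode == "round_robin") {
      part <- collapse_mlgs(ss, loci[-i])
      idx <- part$representative
    } else {
      idx <- seq_len(n_samples(ss))
    }
    a <- c(ss$data[[paste0(loci[i], "_1")]][idx],
           ss$data[[paste0(loci[i], "_2")]][idx])
    tab <- table(a)
    out[[i]] <- as.numeric(tab) / sum(tab)
    names(out[[i]]) <- names(tab)
  }
  structure(out, class = "allele_freq_table", estimation_mode = mode)
}

#' @rdname allele_freqs
#' @export
round_robin_freqs <- function(ss) allele_freqs(ss, "round_robin")

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("Allele frequency table (", attr(x, "estimation_mode"), "), ",
      length(x), " loci\n", sep = "")
  for (loc in names(x)) {
    cat(" ", loc, ": ",
        paste(sprintf("%s=%.3f", names(x[[loc]]), x[[loc]]), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Probability of a multilocus genotype under Hardy-Weinberg (Pgen)
#'
#' Parks & Werth: Pgen = prod over loci of (f_a * f_b) * 2^h, where f_a, f_b
#' are the two allele frequencies at the locus and h is the number of
#' heterozygous loci. Computed in log space for numerical stability.
#'
#' @param genotype Integer matrix L x 2 (one row per locus, canonical allele
#'   pair) or a length-2L vector interleaved per locus.
#' @param freqs An `allele_freq_table` whose loci match the genotype order.
#' @return Probability in (0, 1].
#' @export
pgen <- function(genotype, freqs) {
  if (is.null(dim(genotype)))
    genotype <- matrix(genotype, ncol = 2L, byrow = TRUE)
  L <- nrow(genotype)
  if (L != length(freqs))
    stop("genotype has ", L, " loci but the frequency table has ",
         length(freqs))
  logp <- 0
  h <- 0L
  for (i in seq_len(L)) {
    f <- freqs[[i]]
    fa <- f[as.character(genotype[i, 1L])]
    fb <- f[as.character(genotype[i, 2L])]
    if (is.na(fa) || is.na(fb))
      stop("allele absent from frequency table at locus ", names(freqs)[i],
           " (frequency table does not match the data)")
    logp <- logp + log(fa) + log(fb)
    if (genotype[i, 1L] != genotype[i, 2L]) h <- h + 1L
  }
  unname(exp(logp + h * log(2)))
}

#' Pgen for every sample of a set
#'
#' @param ss A `sample_set` (strict mode).
#' @param freqs An `allele_freq_table`; default round-robin frequencies of
#'   `ss`.
#' @return Named numeric vector of per-sample Pgen values.
#' @export
pgen_samples <- function(ss, freqs = round_robin_freqs(ss)) {
  gm <- genotype_matrix(ss)
  vapply(seq_len(nrow(gm)), function(r) {
    pgen(matrix(gm[r, ], ncol = 2L, byrow = TRUE), freqs)
  }, numeric(1)) |> stats::setNames(ss$data$sample_id)
}

#' Probability of repeated sexual origin of an MLG (Psex)
#'
#' The binomial upper tail: Psex = sum_{i=n}^{N} C(N,i) Pgen^i (1-Pgen)^{N-i},
#' the probability that an MLG with occurrence probability Pgen arises n or
#' more times among N independent sexual events. Computed via the stable
#' binomial survival function. The alternative convention (n-1 additional
#' encounters beyond the first) is available but not the default.
#'
#' @param p_gen Pgen of the MLG, in \[0, 1\].
#' @param n Observed number of copies of the MLG (1 <= n <= N).
#' @param N Number of samples.
#' @param convention `"n"` (default, sum starts at n) or `"n_minus_1"`.
#' @return Probability in \[0, 1\].
#' @export
psex <- function(p_gen, n, N, convention = c("n", "n_minus_1")) {
  convention <- match.arg(convention)
  if (n < 1L || n > N) stop("need 1 <= n <= N")
  if (p_gen < 0 || p_gen > 1) stop("p_gen must be in [0, 1]")
  k <- if (convention == "n") n else n - 1L
  if (k == 0L) return(1)
  stats::pbinom(k - 1L, size = N, prob = p_gen, lower.tail = FALSE)
}
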