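#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats rnorm runif rbinom rpois rnbinom median sd var t.test
#'   pt p.adjust setNames quantile
#' @importFrom utils head
NULL

# data.table NSE columns / tidy-eval pronouns used across the package
utils::globalVariables(c(
  ".", ".N", ".SD", "kmer", "rid", "oid", "start0", "mm", "family",
  "off", "n_loci", "n_fam", "anchor", "side", "J"
))

.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector of A/C/G/T (and N) sequences.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Derive a child seed from a master seed
#'
#' Fixed arithmetic derivation so each simulated library draws from its own
#' stream: adding a library never perturbs the reads of another. Results stay
#' below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param idx integer stream index (>= 0); streams with different `idx` are
#'   independent for practical purposes.
#' @return a single integer seed.
#' @export
child_seed <- function(master, idx) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 48271 + as.numeric(idx) * 104729 + 1) %% m)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# substitution errors applied in-place at a fixed per-base rate
apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < error_rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1L), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# count character mismatches between equal-length string pairs
count_mismatches <- function(a, b) {
  if (!length(a)) return(integer(0))
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
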