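#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All generators in the package are pure functions of (parameters, seed):
#' they draw from a private RNG stream and leave the global stream untouched.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a global seed by stable string hashing
#'
#' Stage insertion must not shift the RNG streams of other stages, so each
#' stage seed depends only on (global seed, stage name). The result is kept
#' below 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return Integer seed for the stage.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1000003L
  as.integer((as.numeric(seed) %% 2147480000 + h * 1009) %% 2147483629)
}

clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings (base implementation, ACGTN alphabet)
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# mutate a sequence at a fixed per-base rate; returns list(seq, positions) with
# 1-based positions of introduced substitutions
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  list(seq = paste(chars, collapse = ""), positions = hit)
}
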