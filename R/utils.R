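# Shared internal helpers.
#
# Coordinate convention: every user-facing position or interval in this
# package (annotation intervals, fold constraints, error messages) is
# 0-based, half-open [start, end). Internally R vectors are 1-based; the
# conversion happens at the interface.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

collapse <- function(v) paste0(v, collapse = "")

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded operations do not perturb the global random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  code
}

NUCS <- c("A", "C", "G", "U")

# allowed (canonical + wobble) base pairs; N never pairs
ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

is_allowed_pair <- function(a, b) paste0(a, b) %in% ALLOWED_PAIRS

# partners an allowed pair permits for a given 5' base
PARTNERS <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))

normalize_seq <- function(seq) {
  s <- toupper(seq)
  gsub("T", "U", s, fixed = TRUE)
}

check_seq_alphabet <- function(seq, id = "<sequence>") {
  bad <- setdiff(unique(chars(seq)), c(NUCS, "N"))
  if (length(bad) > 0)
    stopf("record '%s': invalid sequence character(s): %s", id,
          paste(bad, collapse = ", "))
  invisible(TRUE)
}

# Parse a dot-bracket string into an n x 2 matrix of 1-based pair indices
# (i < j). Errors (with 0-based position) on unbalanced brackets.
db_pairs <- function(structure, id = "<structure>") {
  cs <- chars(structure)
  bad <- setdiff(unique(cs), c("(", ")", "."))
  if (length(bad) > 0)
    stopf("record '%s': invalid structure character(s): %s", id,
          paste(bad, collapse = ", "))
  n <- length(cs)
  stack <- integer(n)
  top <- 0L
  out <- matrix(0L, nrow = n %/% 2L, ncol = 2L)
  k <- 0L
  for (i in seq_len(n)) {
    if (cs[i] == "(") {
      top <- top + 1L
      stack[top] <- i
    } else if (cs[i] == ")") {
      if (top == 0L)
        stopf("record '%s': unbalanced ')' at position %d", id, i - 1L)
      k <- k + 1L
      out[k, ] <- c(stack[top], i)
      top <- top - 1L
    }
  }
  if (top > 0L)
    stopf("record '%s': unmatched '(' at position %d", id, stack[top] - 1L)
  out[seq_len(k), , drop = FALSE]
}

validate_pair <- function(seq, structure, id = "<record>") {
  if (nchar(seq) != nchar(structure))
    stopf("record '%s': sequence length %d != structure length %d",
          id, nchar(seq), nchar(structure))
  check_seq_alphabet(seq, id)
  db_pairs(structure, id)
  invisible(TRUE)
}

# deterministic formatting for branch lengths written into Newick text
fmt_num <- function(x) sprintf("%.12g", x)
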