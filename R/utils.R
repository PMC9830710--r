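# Internal helpers shared across modules.

#' @import tibble
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr arrange bind_rows case_when desc distinct filter group_by
#'   left_join mutate n pull rename row_number select slice summarise ungroup
#' @importFrom stats median rnorm runif setNames
NULL

# Reverse complement of plain ACGTN character vectors. Biostrings owns the
# alphabet semantics; N maps to N.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All simulator randomness flows through this
# so that nothing depends on (or perturbs) global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Total overlap (bp) between the interval [start, end) and a set of intervals
# given as a two-column matrix (start, end), all 0-based half-open.
interval_overlap_total <- function(start, end, ivs) {
  if (is.null(ivs) || nrow(ivs) == 0L) return(0L)
  ov <- pmin(ivs[, 2L], end) - pmax(ivs[, 1L], start)
  sum(pmax(ov, 0L))
}

# Integer median per the chaining convention: odd count -> middle value,
# even count -> floor of the mean of the two central values.
int_median <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n == 0L) return(NA_integer_)
  if (n %% 2L == 1L) as.integer(x[(n + 1L) / 2L]) else
    as.integer((x[n / 2L] + x[n / 2L + 1L]) %/% 2)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) warn(sprintf(fmt, ...))
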