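#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join distinct bind_rows n row_number across rename count
#'   first last if_else case_when pull slice transmute anti_join semi_join
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats fisher.test p.adjust t.test density rpois rbinom rbeta
#'   runif rnorm median var sd approx plogis qlogis setNames dhyper pnorm
#' @importFrom utils head tail
NULL

# Evaluate `code` under a seeded RNG without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_columns <- function(df, cols, arg = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", arg))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_counts <- function(x, what) {
  if (any(is.na(x))) abort(sprintf("%s contains missing values.", what))
  if (any(x < 0)) abort(sprintf("%s contains negative values.", what))
  if (any(x != floor(x))) abort(sprintf("%s contains non-integer values.", what))
  invisible(x)
}

check_probability <- function(p, what = "p") {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", what))
  }
  invisible(p)
}

# Sample odds ratio for a 2x2 table with the +Inf/0 conventions documented in
# overlap_enrichment(); the conditional-MLE estimate from fisher.test is not used.
sample_odds_ratio <- function(a, b, c, d) {
  if ((b == 0 || c == 0) && a > 0 && d >= 0) return(Inf)
  if (b == 0 || c == 0) return(NaN)
  (a * d) / (b * c)
}
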