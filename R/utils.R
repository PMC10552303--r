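#' @keywords internal
"_PACKAGE"

# Structured one-line stage log. Every filtering/threshold step goes through
# this so a run can be audited from its log alone.
log_stage <- function(stage, ...) {
  kv <- list(...)
  if (length(kv)) {
    parts <- vapply(seq_along(kv), function(i) {
      paste0(names(kv)[i], "=", paste(format(kv[[i]]), collapse = ","))
    }, character(1))
    message(sprintf("[fetomics] %s %s", stage, paste(parts, collapse = " ")))
  } else {
    message(sprintf("[fetomics] %s", stage))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Average-rank helper shared by Spearman routines and score aggregation.
avg_rank <- function(x) rank(x, ties.method = "average")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
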