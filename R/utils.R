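#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rexp rlnorm rnbinom runif median pchisq pnorm pt
#'   qnorm glm binomial coef vcov fisher.test wilcox.test setNames
#'   complete.cases
#' @importFrom utils write.table read.table head modifyList
NULL

# Derive a per-stage RNG seed from the global seed so stages can be rerun
# independently without sharing a stream. Kept < 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 101L, survival = 202L, calls = 303L, counts = 404L,
               framework = 505L, pipeline = 606L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

# Deterministic TSV writer used by all pipeline outputs: fixed column order,
# no quoting, "NA" for missing, and a comment header recording provenance.
write_tsv <- function(df, path, header_fields = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header_fields)) {
    writeLines(paste0("# ", paste(names(header_fields), unlist(header_fields),
                                  sep = "=", collapse = " ")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, ...)
}
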