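#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test fisher.test kruskal.test plogis qlogis
#'   aov anova rbeta rbinom rnorm runif sd shapiro.test t.test wilcox.test
#'   pt quantile median complete.cases setNames dhyper
#' @importFrom utils read.delim write.table
NULL

# deterministic child seeds so stages can be re-run independently
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) * 7919L
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# character matrix (positions x reads) from equal-length strings
seq_matrix <- function(x) {
  if (length(x) == 0) return(matrix(character(0), nrow = 0, ncol = 0))
  n <- nchar(x[1])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = length(x))
}

collapse_matrix <- function(m) {
  if (ncol(m) == 0) return(character(0))
  do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
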