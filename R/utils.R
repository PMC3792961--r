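# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats rnorm runif sd setNames approx
#' @importFrom utils read.table write.table
NULL

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

# Parse a CIGAR string into a data.frame of (len, op). "*" yields zero rows.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(data.frame(len = integer(0), op = character(0)))
  }
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar, perl = TRUE)
  if (m[[1]][1] == -1 || sum(attr(m[[1]], "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  toks <- regmatches(cigar, m)[[1]]
  data.frame(
    len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    op  = sub("^[0-9]+", "", toks),
    stringsAsFactors = FALSE
  )
}

# Number of read bases consumed by a CIGAR (M, I, S, =, X).
cigar_read_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])

# Vectorized read-length check over many CIGAR strings.
cigar_read_lens <- function(cigars) {
  m <- gregexpr("[0-9]+[MIS=X]", cigars)
  vapply(regmatches(cigars, m), function(tk) {
    if (length(tk) == 1 && is.na(tk)) return(0L)
    sum(as.integer(sub("[MIS=X]$", "", tk)))
  }, integer(1))
}

# Number of reference bases consumed (M, D, N, =, X).
cigar_ref_span <- function(ops) sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])

# Phred qualities from a SAM quality string (offset 33 unless stated).
qual_to_int <- function(qual, offset = 33L) {
  if (is.na(qual) || qual == "*") return(integer(0))
  utf8ToInt(qual) - as.integer(offset)
}

int_to_qual <- function(q, offset = 33L) {
  if (length(q) == 0) return("*")
  intToUtf8(as.integer(q) + as.integer(offset))
}

is_reverse <- function(flag) bitwAnd(as.integer(flag), 16L) != 0L
is_paired <- function(flag) bitwAnd(as.integer(flag), 1L) != 0L
is_first_mate <- function(flag) bitwAnd(as.integer(flag), 64L) != 0L
is_unmapped <- function(flag) bitwAnd(as.integer(flag), 4L) != 0L
mate_unmapped <- function(flag) bitwAnd(as.integer(flag), 8L) != 0L

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the length-1 surprise
safe_sample <- function(x, size = length(x)) x[sample.int(length(x), size)]
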