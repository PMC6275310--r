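# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Separator used in internal dyad keys; identifiers may not contain it.
.EDGE_SEP <- "\037"

# C-collation sort so canonical orderings do not depend on the session locale.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

empty_edge_matrix <- function() {
  matrix(character(), nrow = 0L, ncol = 2L, dimnames = list(NULL, c("a", "b")))
}

# Canonicalise a two-column character matrix of unordered pairs: endpoints
# sorted within a row (C collation), duplicate rows dropped, rows sorted.
canonical_edge_matrix <- function(m) {
  if (is.null(m) || nrow(m) == 0L) {
    return(empty_edge_matrix())
  }
  lev <- sort_c(unique(as.vector(m)))
  ia <- match(m[, 1L], lev)
  ib <- match(m[, 2L], lev)
  swap <- ia > ib
  a <- ifelse(swap, m[, 2L], m[, 1L])
  b <- ifelse(swap, m[, 1L], m[, 2L])
  keep <- !duplicated(paste(a, b, sep = .EDGE_SEP))
  a <- a[keep]
  b <- b[keep]
  o <- order(match(a, lev), match(b, lev))
  out <- cbind(a[o], b[o])
  dimnames(out) <- list(NULL, c("a", "b"))
  out
}

# All unordered pairs within a set of identifiers, canonical form.
pairs_within <- function(ids) {
  ids <- sort_c(unique(as.character(ids)))
  if (length(ids) < 2L) {
    return(empty_edge_matrix())
  }
  out <- t(utils::combn(ids, 2L))
  dimnames(out) <- list(NULL, c("a", "b"))
  out
}

pair_keys <- function(m) {
  if (nrow(m) == 0L) return(character())
  paste(m[, 1L], m[, 2L], sep = .EDGE_SEP)
}

keys_to_matrix <- function(keys) {
  if (length(keys) == 0L) return(empty_edge_matrix())
  parts <- strsplit(keys, .EDGE_SEP, fixed = TRUE)
  out <- cbind(
    vapply(parts, `[[`, character(1L), 1L),
    vapply(parts, `[[`, character(1L), 2L)
  )
  dimnames(out) <- list(NULL, c("a", "b"))
  out
}

check_ids <- function(x, what) {
  x <- as.character(x)
  if (length(x) == 0L) {
    stop(sprintf("at least one %s identifier is required", what), call. = FALSE)
  }
  if (anyNA(x) || any(!nzchar(x))) {
    stop(sprintf("%s identifiers must be non-missing, non-empty strings", what),
         call. = FALSE)
  }
  if (any(grepl(.EDGE_SEP, x, fixed = TRUE))) {
    stop(sprintf("%s identifiers may not contain control characters", what),
         call. = FALSE)
  }
  x
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == trunc(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

# Write lines as UTF-8 with "\n" terminators regardless of platform, so equal
# objects always serialise to byte-identical files.
write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
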