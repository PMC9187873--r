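# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) if (!isTRUE(cond)) .stopf(fmt, ...)

#' @noRd
.as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

# Symmetric Dirichlet draw (concentration 1 = flat simplex by default).
.rdirichlet <- function(n, k, alpha = 1) {
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), nrow = n)
  # guard against all-zero rows at tiny alpha
  g[rowSums(g) == 0, ] <- 1
  g / rowSums(g)
}

# Euclidean projection of each column of V onto the probability simplex
# (sort-based algorithm, fully vectorised over columns: one radix sort and
# one global cumsum; the support of the projection is a prefix of the
# sorted column, so its size is a column sum).
.project_simplex_cols <- function(V) {
  k <- nrow(V); n <- ncol(V)
  if (k == 1L) return(matrix(1, 1L, n, dimnames = dimnames(V)))
  o <- order(col(V), V, method = "radix", decreasing = c(FALSE, TRUE))
  U <- matrix(V[o], k, n)
  cs <- matrix(cumsum(U), k, n)
  if (n > 1L) cs <- cs - rep(c(0, cs[k, -n]), each = k)
  cond <- U - (cs - 1) / seq_len(k) > 0
  rho <- colSums(cond)
  theta <- (cs[cbind(rho, seq_len(n))] - 1) / rho
  W <- pmax(sweep(V, 2L, theta, "-"), 0)
  dimnames(W) <- dimnames(V)
  W
}

# FNV-1a 32-bit hash of a character scalar; used to stamp outputs with a
# configuration fingerprint without external digest dependencies.
.fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(low8, b)  # b < 256: xor touches the low byte only
    # 32-bit modular multiply, split to stay within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.config_hash <- function(params) {
  .fnv1a32(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA))
}

# Header comment lines stamped on every TSV artifact.
.tsv_header <- function(kind, params = NULL) {
  lines <- c(
    sprintf("# subpopscreen %s", as.character(utils::packageVersion("subpopscreen"))),
    sprintf("# kind: %s", kind)
  )
  if (!is.null(params) && length(params)) {
    pj <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
    lines <- c(lines,
               sprintf("# params: %s", pj),
               sprintf("# config: %s", .fnv1a32(pj)))
  }
  lines
}

# Read a TSV written by write_results(): returns list(header, table).
.read_tsv_with_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  body <- if (length(hdr)) lines[-hdr] else lines
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  list(header = lines[hdr], table = tab)
}

.write_tsv_with_header <- function(df, path, kind, params = NULL, digits = 12) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsv_header(kind, params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
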