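#' Construct a fingerprint matrix
#'
#' A `fingerprint_matrix` holds one binary fingerprint per compound: an
#' n x d 0/1 matrix with compound ids as row names and a kind tag. Two kinds
#' are recognized: `"keyed-166"` (a 166-bit keyed substructure set, MACCS
#' style, width enforced at 166) and `"hashed-path"` (a hashed path-based
#' fingerprint, CDK style; default width 1024, configurable).
#'
#' @param bits 0/1 matrix (or object coercible to one), compounds in rows.
#' @param ids character vector of unique compound ids, one per row.
#' @param kind `"keyed-166"` or `"hashed-path"`.
#' @return a `fingerprint_matrix` object.
#' @export
fingerprint_matrix <- function(bits, ids, kind = c("hashed-path", "keyed-166")) {
  kind <- match.arg(kind)
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (nrow(bits) != length(ids)) {
    stop("`ids` must have one entry per fingerprint row.", call. = FALSE)
  }
  if (length(bits) > 0 && !all(bits %in% c(0L, 1L))) {
    stop("Fingerprint entries must all be 0 or 1.", call. = FALSE)
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("Duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (kind == "keyed-166" && ncol(bits) != 166) {
    stop("keyed-166 fingerprints must be 166 bits wide, got ", ncol(bits), ".",
         call. = FALSE)
  }
  rownames(bits) <- ids
  structure(list(ids = ids, bits = bits, kind = kind),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat("<fingerprint_matrix> ", nrow(x$bits), " compounds x ", ncol(x$bits),
      " bits (", x$kind, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.fingerprint_matrix <- function(x) dim(x$bits)

#' Subset a fingerprint matrix by compound id or row index
#'
#' @param fp a `fingerprint_matrix`.
#' @param i row indices or compound ids.
#' @return a `fingerprint_matrix` with the selected rows, in request order.
#' @export
fp_subset <- function(fp, i) {
  stopifnot(inherits(fp, "fingerprint_matrix"))
  if (is.character(i)) {
    miss <- setdiff(i, fp$ids)
    if (length(miss) > 0) {
      stop("Unknown compound id(s): ", paste(utils::head(miss, 5), collapse = ", "),
           call. = FALSE)
    }
    i <- match(i, fp$ids)
  }
  fingerprint_matrix(fp$bits[i, , drop = FALSE], fp$ids[i], fp$kind)
}

#' Bind two fingerprint matrices row-wise
#'
#' @param a,b `fingerprint_matrix` objects of the same kind and width.
#' @return combined `fingerprint_matrix`.
#' @export
fp_rbind <- function(a, b) {
  stopifnot(inherits(a, "fingerprint_matrix"), inherits(b, "fingerprint_matrix"))
  if (a$kind != b$kind || ncol(a$bits) != ncol(b$bits)) {
    stop("Fingerprint kinds/widths differ.", call. = FALSE)
  }
  fingerprint_matrix(rbind(a$bits, b$bits), c(a$ids, b$ids), a$kind)
}

#' Read a fingerprint table from delimited text
#'
#' Two layouts are auto-detected from the first data row: (a) two columns
#' `compound_id`, `bitstring` where the bitstring is a contiguous run of 0/1
#' characters, or (b) an id column followed by d single-bit columns. A
#' header row is optional for layout (a) and detected by a non-binary
#' second field.
#'
#' @param path file path.
#' @param kind fingerprint kind tag to attach, see [fingerprint_matrix()].
#' @return a `fingerprint_matrix`.
#' @export
read_fingerprints <- function(path, kind = c("hashed-path", "keyed-166")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("File not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("Fingerprint file ", path, " is empty.", call. = FALSE)
  }
  delim <- if (grepl("\t", lines[[1]])) "\t" else ","
  cells <- strsplit(lines, delim, fixed = TRUE)
  first <- cells[[1]]
  is_bits <- function(x) grepl("^[01]+$", x)
  # drop a header row: recognized by letters in the second field (a corrupt
  # all-digit bitstring is a data error, not a header)
  if (length(first) >= 2 && grepl("[A-Za-z]", first[[2]])) {
    cells <- cells[-1]
    if (length(cells) == 0) {
      stop("Fingerprint file ", path, " has a header but no rows.", call. = FALSE)
    }
  }
  ids <- character(length(cells))
  rows <- vector("list", length(cells))
  for (r in seq_along(cells)) {
    f <- trimws(cells[[r]])
    ids[[r]] <- f[[1]]
    body <- f[-1]
    if (any(!is_bits(body))) {
      stop("Non-binary symbol in fingerprint row ", r, " (id ", f[[1]], ") of ",
           path, ".", call. = FALSE)
    }
    if (length(body) == 1) {
      rows[[r]] <- as.integer(strsplit(body, "")[[1]])
    } else {
      rows[[r]] <- as.integer(body)
    }
  }
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) {
    off <- which(widths != widths[[1]])[[1]]
    stop("Ragged fingerprint rows in ", path, ": row ", off, " (id ", ids[[off]],
         ") has ", widths[[off]], " bits, expected ", widths[[1]], ".",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("Duplicate compound id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  fingerprint_matrix(do.call(rbind, rows), ids, kind)
}

#' Write a fingerprint table as delimited text
#'
#' Emits the compact two-column layout (`compound_id,bitstring`) with a
#' header; [read_fingerprints()] round-trips it bit-exactly.
#'
#' @param fp a `fingerprint_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fp, path) {
  stopifnot(inherits(fp, "fingerprint_matrix"))
  bitstrings <- apply(fp$bits, 1, paste, collapse = "")
  if (nrow(fp$bits) == 0) bitstrings <- character(0)
  writeLines(c("compound_id,bitstring", paste(fp$ids, bitstrings, sep = ",")),
             path)
  invisible(path)
}

# --- pluggable chemistry backend ---------------------------------------------

.vsratio_env <- new.env(parent = emptyenv())

#' Register a fingerprinting backend
#'
#' Structure-to-fingerprint computation is delegated to a pluggable backend
#' (for example an RDKit or OpenBabel bridge) rather than re-implemented.
#' A backend is a function `f(structures, kind, width)` returning a 0/1
#' matrix with one row per parseable structure and `NA` rows for failures.
#'
#' @param backend the backend function, or `NULL` to unregister.
#' @return the previously registered backend, invisibly.
#' @export
register_fingerprint_backend <- function(backend) {
  old <- .vsratio_env$fp_backend
  stopifnot(is.null(backend) || is.function(backend))
  .vsratio_env$fp_backend <- backend
  invisible(old)
}

#' Compute fingerprints from structure line notation
#'
#' Runs the registered chemistry backend over a vector of structure strings
#' (e.g. SMILES). Unparseable structures are reported with a warning and
#' skipped, so the result has one row per successfully fingerprinted
#' structure.
#'
#' @param structures character vector of line-notation structures; names, if
#'   present, become compound ids (otherwise `s1 ... sn`).
#' @param kind fingerprint kind, see [fingerprint_matrix()].
#' @param width bit width for `"hashed-path"` (ignored for `"keyed-166"`).
#' @return a `fingerprint_matrix`.
#' @export
compute_fingerprints <- function(structures, kind = c("hashed-path", "keyed-166"),
                                 width = 1024) {
  kind <- match.arg(kind)
  backend <- .vsratio_env$fp_backend
  if (is.null(backend)) {
    stop("No fingerprint backend registered; see `register_fingerprint_backend()`.",
         call. = FALSE)
  }
  d <- if (kind == "keyed-166") 166L else as.integer(width)
  ids <- names(structures)
  if (is.null(ids)) ids <- paste0("s", seq_along(structures))
  if (length(structures) == 0) {
    return(fingerprint_matrix(matrix(integer(0), 0, d), character(0), kind))
  }
  bits <- backend(structures, kind, d)
  bits <- as.matrix(bits)
  failed <- apply(bits, 1, function(r) any(is.na(r)))
  if (any(failed)) {
    warning(sum(failed), " structure(s) could not be fingerprinted and were skipped: ",
            paste(utils::head(ids[failed], 5), collapse = ", "), call. = FALSE)
  }
  fingerprint_matrix(bits[!failed, , drop = FALSE], ids[!failed], kind)
}

# --- similarity ---------------------------------------------------------------

#' Tanimoto similarity between two binary fingerprints
#'
#' `|a AND b| / |a OR b|`, the standard chemical similarity on bit sets.
#' Two all-zero fingerprints are defined as identical (similarity 1), which
#' avoids 0/0 while preserving reflexivity.
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0), c(0, 1, 1)) # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("Fingerprints have different lengths (", length(a), " vs ",
         length(b), ").", call. = FALSE)
  }
  a <- as.integer(a); b <- as.integer(b)
  if (!all(a %in% c(0L, 1L)) || !all(b %in% c(0L, 1L))) {
    stop("Fingerprints must be binary.", call. = FALSE)
  }
  union_n <- sum(a | b)
  if (union_n == 0) {
    return(1)
  }
  sum(a & b) / union_n
}

#' Maximum Tanimoto similarity of each query to a reference set
#'
#' For each row of `query`, the largest Tanimoto similarity to any row of
#' `reference` (the "nearest active" similarity used to characterize decoy
#' hardness).
#'
#' @param query,reference `fingerprint_matrix` objects or 0/1 matrices of
#'   equal bit width.
#' @return numeric vector, one maximum per query row.
#' @export
max_tanimoto <- function(query, reference) {
  q <- if (inherits(query, "fingerprint_matrix")) query$bits else as.matrix(query)
  r <- if (inherits(reference, "fingerprint_matrix")) reference$bits else as.matrix(reference)
  if (ncol(q) != ncol(r)) {
    stop("Bit widths differ (", ncol(q), " vs ", ncol(r), ").", call. = FALSE)
  }
  storage.mode(q) <- "integer"
  storage.mode(r) <- "integer"
  max_tanimoto_cpp(q, r)
}
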