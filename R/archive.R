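# 64-bit code handling and the monogram archive container.
#
# Bit convention (fixed, round-trip tested): the bit at monogram cell
# (i, j) occupies position 8*(i-1) + (j-1) counting from the most
# significant bit of the 16-character lowercase hex string. Equivalently,
# the hex string reads the 8x8 matrix row by row, left to right.

hex_digits <- c(0:9, letters[1:6])

#' Convert binary monograms to 16-character hex codes
#'
#' @param bits length-64 0/1 vector, an 8x8 binary matrix, or an n x 64
#'   matrix of row-major codes.
#' @return Character vector of lowercase 16-hex-digit codes.
#' @examples
#' bits_to_hex(c(1, rep(0, 63)))  # bit at cell (1,1) -> "8000..."
#' @export
bits_to_hex <- function(bits) {
  if (is.matrix(bits) && nrow(bits) == 8L && ncol(bits) == 8L) {
    bits <- matrix(as.integer(t(bits)), nrow = 1L)
  } else if (!is.matrix(bits)) {
    if (length(bits) != 64L) stop("codes must have exactly 64 bits")
    bits <- matrix(as.integer(bits), nrow = 1L)
  }
  if (ncol(bits) != 64L) stop("codes must have exactly 64 bits")
  if (!all(bits %in% c(0L, 1L))) stop("codes must be 0/1")
  # nibble k collects bits 4(k-1)+1 .. 4k, first bit most significant
  P <- matrix(0L, 64L, 16L)
  for (k in seq_len(16L)) P[4L * (k - 1L) + 1:4, k] <- c(8L, 4L, 2L, 1L)
  nib <- bits %*% P
  chars <- matrix(hex_digits[nib + 1L], nrow(bits), 16L)
  do.call(paste0, asplit(chars, 2L))
}

#' Convert hex codes back to bit matrices
#'
#' Inverse of [bits_to_hex()].
#'
#' @param hex character vector of 16-hex-digit codes.
#' @return n x 64 integer 0/1 matrix (row-major bit order).
#' @export
hex_to_bits <- function(hex) {
  hex <- tolower(as.character(hex))
  if (!all(grepl("^[0-9a-f]{16}$", hex))) {
    stop("codes must be 16 hexadecimal characters")
  }
  nib <- vapply(strsplit(hex, ""), function(ch) strtoi(ch, 16L),
                integer(16L))
  if (is.null(dim(nib))) nib <- matrix(nib, nrow = 16L)
  out <- matrix(0L, length(hex), 64L)
  for (k in seq_len(16L)) {
    v <- nib[k, ]
    out[, 4L * (k - 1L) + 1:4] <- cbind(v %/% 8L, (v %/% 4L) %% 2L,
                                        (v %/% 2L) %% 2L, v %% 2L)
  }
  out
}

#' Construct a monogram archive
#'
#' The searchable store of encoded patients: one record per patient with
#' its diagnosis label and 64-bit binary monogram, plus (optionally) the
#' real-valued monograms for real-vs-binary comparisons.
#'
#' @param patient_id unique character ids.
#' @param labels diagnosis label per patient.
#' @param bits n x 64 integer 0/1 matrix (row-major codes), or a character
#'   vector of 16-hex-digit codes.
#' @param real optional n x 64 numeric matrix of real-valued monograms.
#' @return An object of class `"monogram_archive"` with elements
#'   `patient_id`, `label`, `bits`, `real`.
#' @export
monogram_archive <- function(patient_id, labels, bits, real = NULL) {
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id)) stop("duplicate patient_id in archive")
  if (is.character(bits)) bits <- hex_to_bits(bits)
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  dimnames(bits) <- NULL
  if (ncol(bits) != 64L) stop("codes must have exactly 64 bits")
  if (nrow(bits) != length(patient_id)) stop("one code per patient required")
  if (!all(bits %in% c(0L, 1L))) stop("codes must be 0/1")
  if (!is.null(real)) {
    real <- as.matrix(real)
    dimnames(real) <- NULL
    stopifnot(nrow(real) == length(patient_id), ncol(real) == 64L)
  }
  structure(
    list(patient_id = patient_id, label = as.character(labels),
         bits = bits, real = real),
    class = "monogram_archive"
  )
}

#' @export
print.monogram_archive <- function(x, ...) {
  cat("<monogram_archive> ", length(x$patient_id), " records, ",
      length(unique(x$label)), " classes",
      if (!is.null(x$real)) "; real monograms retained" else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of records in an archive
#' @param archive a [monogram_archive()].
#' @return Integer count.
#' @export
archive_size <- function(archive) length(archive$patient_id)

#' Hex codes of an archive's records
#' @param archive a [monogram_archive()].
#' @return Character vector of 16-hex-digit codes, named by patient id.
#' @export
archive_codes <- function(archive) {
  stats::setNames(bits_to_hex(archive$bits), archive$patient_id)
}

#' Write an archive to CSV
#'
#' Columns `patient_id,label,code_hex` with the 16-hex-digit code; the
#' round trip through [read_archive()] is bit-exact. Real-valued
#' monograms are not serialized.
#'
#' @param archive a [monogram_archive()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_archive <- function(archive, path) {
  data.table::fwrite(
    data.table::data.table(patient_id = archive$patient_id,
                           label = archive$label,
                           code_hex = bits_to_hex(archive$bits)),
    path
  )
  invisible(path)
}

#' Read an archive from CSV
#'
#' @param path a CSV written by [write_archive()] (columns
#'   `patient_id,label,code_hex`).
#' @return A [monogram_archive()].
#' @export
read_archive <- function(path) {
  dt <- data.table::fread(path, colClasses = "character")
  need <- c("patient_id", "label", "code_hex")
  if (!all(need %in% names(dt))) {
    stop("archive file must have columns ", paste(need, collapse = ", "))
  }
  monogram_archive(dt$patient_id, dt$label, dt$code_hex)
}
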