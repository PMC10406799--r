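# Compressed-stream container: a small self-describing format so
# compressed byte counts are concrete and reconstructions can be reproduced
# from the stream alone.
#
#   bytes 1-4   magic "CAVC"
#   bytes 5-8   header length (uint32, little endian)
#   header      JSON: encoder, dim, bit_depth, spacing, params
#   payload     gzip-packed little-endian int32 quantized coefficients

BITSTREAM_MAGIC <- charToRaw("CAVC")

build_bitstream <- function(encoder_id, raw, params, payload) {
  hdr <- jsonlite::toJSON(
    list(encoder = encoder_id, dim = dim(raw$data),
         bit_depth = raw$bit_depth, spacing = raw$spacing,
         params = params),
    auto_unbox = TRUE, digits = NA)
  hdr_raw <- charToRaw(as.character(hdr))
  c(BITSTREAM_MAGIC,
    writeBin(length(hdr_raw), raw(), size = 4L, endian = "little"),
    hdr_raw,
    payload)
}

parse_bitstream <- function(stream) {
  if (!identical(stream[1:4], BITSTREAM_MAGIC))
    stop("not a compressed-stack container (bad magic bytes)")
  hlen <- readBin(stream[5:8], "integer", size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(stream[8L + seq_len(hlen)]))
  payload <- stream[-seq_len(8L + hlen)]
  list(header = header, payload = payload)
}

#' Write / read a compressed stack container
#'
#' `write_bitstream()` stores a `compression_result`'s packed stream in a
#' small self-describing container (magic bytes, JSON header with shape,
#' bit depth and coding parameters, gzip payload). `read_bitstream()`
#' parses the container and fully re-decodes the reconstruction from the
#' quantized coefficients, returning a [volume_stack()].
#'
#' @param result A `compression_result` from [encode_target_psnr()],
#'   [encode_qp_matched()] or [encode_lossless()].
#' @param path File path for the container.
#' @return `read_bitstream()` returns the reconstructed [volume_stack()];
#'   `write_bitstream()` returns `path` invisibly.
#' @export
write_bitstream <- function(result, path) {
  stopifnot(inherits(result, "compression_result"))
  if (is.null(result$stream)) stop("result carries no packed stream")
  writeBin(result$stream, path)
  invisible(path)
}

#' @rdname write_bitstream
#' @export
read_bitstream <- function(path) {
  stream <- readBin(path, "raw", n = file.info(path)$size)
  decode_bitstream(stream)
}

# Decode a container byte stream back to the reconstructed volume.
decode_bitstream <- function(stream) {
  p <- parse_bitstream(stream)
  h <- p$header
  d <- as.integer(h$dim)
  bit_depth <- as.integer(h$bit_depth)
  spacing <- as.numeric(h$spacing)
  peak <- 2^bit_depth - 1
  if (h$encoder == "lossless") {
    int_size <- as.integer(h$params$int_size)
    offset <- as.integer(h$params$offset)
    bytes <- memDecompress(p$payload, type = "gzip")
    vox <- readBin(bytes, "integer", n = length(bytes) %/% int_size,
                   size = int_size, endian = "little") + offset
    return(volume_stack(array(as.numeric(vox), d), bit_depth, spacing))
  }
  qints <- unpack_coeffs(p$payload)

  if (h$encoder == "wavelet") {
    step <- h$params$step
    levels <- as.integer(h$params$levels)
    per_slice <- d[1] * d[2]
    rec <- array(0, d)
    for (s in seq_len(d[3])) {
      qc <- qints[(s - 1L) * per_slice + seq_len(per_slice)]
      ch <- dequantize_deadzone(qc, step)
      dim(ch) <- d[1:2]
      rec[, , s] <- clip(round(haar2_inv(ch, levels)), 0, peak)
    }
  } else if (h$encoder == "predictive") {
    step <- h$params$step
    gop <- as.integer(h$params$gop)
    C <- dct8_matrix()
    pd <- c(d[1] + (8 - d[1] %% 8) %% 8, d[2] + (8 - d[2] %% 8) %% 8)
    per_slice <- pd[1] * pd[2]
    rec <- array(0, d)
    prev <- NULL
    for (s in seq_len(d[3])) {
      intra <- ((s - 1L) %% gop) == 0L
      pred <- if (intra) matrix(0, d[1], d[2]) else prev
      qc <- qints[(s - 1L) * per_slice + seq_len(per_slice)]
      ch <- dequantize_deadzone(qc, step)
      dim(ch) <- pd
      res_hat <- idct2_blocks(ch, C)[seq_len(d[1]), seq_len(d[2]),
                                     drop = FALSE]
      rec_s <- clip(round(pred + res_hat), 0, peak)
      rec[, , s] <- rec_s
      prev <- rec_s
    }
  } else {
    stop(sprintf("unknown encoder id '%s' in container", h$encoder))
  }
  volume_stack(rec, bit_depth, spacing)
}
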