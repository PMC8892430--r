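#' Write a run as indexed mzXML
#'
#' Produces a minimal, valid, indexed mzXML 3.2 document with centroided MS1
#' scans: uncompressed network-byte-order peak arrays (m/z-int interleaved),
#' 32- or 64-bit precision, a scan byte-offset index and `indexOffset`.  The
#' output is readable by standard mzXML parsers (and by [read_run()]).
#'
#' @param run an [ms_run()].
#' @param path output file path.
#' @param precision peak-array encoding, 32 (default, as written by common
#'   converter settings) or 64 bit.
#' @return invisibly, `path`.
#' @export
write_mzxml <- function(run, path, precision = 32L) {
  stopifnot(precision %in% c(32L, 64L))
  n <- length(run$scans)
  head <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2"',
    ' xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"',
    ' xsi:schemaLocation="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2',
    ' http://sashimi.sourceforge.net/schema_revision/mzXML_3.2/mzXML_idx_3.2.xsd">\n',
    sprintf(' <msRun scanCount="%d">\n', n),
    '  <dataProcessing centroided="1"></dataProcessing>\n')
  scan_str <- vapply(seq_len(n), function(i) {
    s <- run$scans[[i]]
    paste0(
      sprintf(paste0('  <scan num="%d" msLevel="%d" peaksCount="%d"',
                     ' polarity="%s" retentionTime="PT%.6fS">\n'),
              i, s$ms_level, length(s$mz), s$polarity, s$rt),
      sprintf(paste0('   <peaks precision="%d" byteOrder="network"',
                     ' contentType="m/z-int" compressionType="none"',
                     ' compressedLen="0">%s</peaks>\n'),
              precision, encode_peaks(s$mz, s$intensity, precision)),
      '  </scan>\n')
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeChar(head, con, eos = NULL)
  pos <- nchar(head, type = "bytes")
  offsets <- numeric(n)
  for (i in seq_len(n)) {
    offsets[i] <- pos
    writeChar(scan_str[i], con, eos = NULL)
    pos <- pos + nchar(scan_str[i], type = "bytes")
  }
  tail1 <- ' </msRun>\n'
  writeChar(tail1, con, eos = NULL)
  pos <- pos + nchar(tail1, type = "bytes")
  idx <- paste0(
    ' <index name="scan">\n',
    paste(sprintf('  <offset id="%d">%.0f</offset>\n', seq_len(n), offsets),
          collapse = ""),
    ' </index>\n',
    sprintf(' <indexOffset>%.0f</indexOffset>\n', pos),
    ' <sha1>0</sha1>\n</mzXML>\n')
  writeChar(idx, con, eos = NULL)
  invisible(path)
}

encode_peaks <- function(mz, intensity, precision) {
  v <- as.numeric(rbind(mz, intensity))
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(v, con, size = precision / 8L, endian = "big")
  ## base64_enc line-wraps long input; peak data must be a single token
  gsub("\n", "", jsonlite::base64_enc(rawConnectionValue(con)), fixed = TRUE)
}
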