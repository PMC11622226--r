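# Writes a tiny centroided imzML/ibd pair in processed mode: per-spectrum
# m/z (float64) and intensity (float32) arrays, external offsets counted
# from the start of the .ibd (after a 16-byte UUID block, as in real files).
write_toy_imzml <- function(stem, spectra) {
  ibd <- paste0(stem, ".ibd")
  imzml <- paste0(stem, ".imzML")
  con <- file(ibd, "wb")
  writeBin(as.raw(1:16), con)                       # UUID placeholder
  offset <- 16
  entries <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    n <- length(sp$mz)
    mz_off <- offset
    writeBin(as.double(sp$mz), con, size = 8L, endian = "little")
    offset <<- offset + 8 * n
    int_off <- offset
    writeBin(as.double(sp$intensity), con, size = 4L, endian = "little")
    offset <<- offset + 4 * n
    list(n = n, mz_off = mz_off, int_off = int_off,
         x = sp$x, y = sp$y)
  })
  close(con)

  spectrum_xml <- vapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i - 1L, e$n, e$x, e$y, e$mz_off, e$n, e$int_off, e$n)
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<run id="run0"><spectrumList count="', length(entries), '">',
    paste(spectrum_xml, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, imzml)
  imzml
}
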