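# Shared reference values: the 15-row accurate-mass annotation table of the
# 60% ethanol fraction (formula, sodiated theoretical/experimental m/z,
# ppm error, nominal fragment ladder, identification), plus small builders.

table2 <- data.frame(
  peak_id = as.character(1:15),
  rt_min = c(29.8, 31.7, 37.6, 38.5, 39.2, 54.9, 56.7, 57.6, 58.0, 58.6,
             60.4, 62.2, 63.9, 64.4, 75.8),
  formula = c("C45H76O20", "C45H74O19", "C45H76O19", "C45H76O19", "C45H76O19",
              "C45H74O18", "C39H64O14", "C39H66O14", "C39H64O14", "C39H64O14",
              "C39H64O14", "C39H64O13", "C39H64O13", "C39H64O13", "C33H54O8"),
  theoretical_mz = c(959.4822, 941.4717, 943.4873, 943.4873, 943.4873,
                     925.4767, 779.4188, 781.4345, 779.4188, 779.4188,
                     779.4188, 763.4239, 763.4239, 763.4239, 601.3711),
  experimental_mz = c(959.4833, 941.4726, 943.4886, 943.4882, 943.4871,
                      925.4788, 779.4202, 781.4367, 779.4189, 779.4184,
                      779.4187, 763.4237, 763.4241, 763.4221, 601.3703),
  error_ppm = c(-1.1, -1.0, -1.4, -1.0, 0.2, -2.3, -1.8, -2.8, -0.1, 0.5,
                0.1, 0.3, -0.3, 2.4, 1.3),
  identification = c("Timosaponin N", "Timosaponin M", "Timosaponin BII",
                     "25R-Timosaponin BII", "25S-Officinalisnin-I",
                     "Timosaponin BIII", "Timosaponin G",
                     "Anemarrhena saponin I", "Isomer of timosaponin G",
                     "25(27)-ene-Anemarrhena saponin I", "Timosaponin A2",
                     "Timosaponin AIV", "Timosaponin AIII",
                     "25R-Timosaponin AIII", "Timosaponin AI"),
  stringsAsFactors = FALSE
)

table2_ladders <- list(
  c(919, 757, 595, 433, 415, 271, 253),
  c(901, 739, 577, 415, 273, 255),
  c(903, 741, 579, 417, 273, 255),
  c(903, 741, 579, 417, 273, 255),
  c(903, 741, 579, 417, 273, 255),
  c(741, 579, 417, 273, 255),
  c(739, 595, 433, 415, 273, 255),
  c(741, 579, 417, 399, 271, 253),
  c(739, 577, 415, 273, 255),
  c(739, 595, 433, 415, 271, 253),
  c(757, 595, 433, 415, 271, 253),
  c(579, 417, 273, 255),
  c(579, 417, 273, 255),
  c(579, 417, 273, 255),
  c(417, 273, 255)
)

authentic_standards <- c("Timosaponin BII", "Timosaponin BIII", "Timosaponin G",
                         "Anemarrhena saponin I", "Timosaponin AIII",
                         "Timosaponin AIV")

table2_peaks_path <- function() {
  system.file("extdata", "table2_peaks.tsv", package = "saponinscreen")
}

random_formula <- function() {
  syms <- sample(c("C", "H", "O", "N", "Na"), sample(2:5, 1))
  counts <- sample(1:60, length(syms), replace = TRUE)
  chem_formula(stats::setNames(counts, syms))
}

# Minimal mzML writer (64-bit floats, no compression) for reader tests.
write_test_mzml <- function(path, specs) {
  enc64 <- function(x) jsonlite::base64_enc(writeBin(x, raw(), size = 8,
                                                     endian = "little"))
  one <- function(index, id, s) {
    b64mz <- enc64(s$mz); b64i <- enc64(s$inten)
    prec <- if (s$mslevel == 2) sprintf(paste0(
      '<precursorList count="1"><precursor><selectedIonList count="1">',
      '<selectedIon><cvParam cvRef="MS" accession="MS:1000744" ',
      'name="selected ion m/z" value="%.6f" unitCvRef="MS" ',
      'unitAccession="MS:1000040" unitName="m/z"/></selectedIon>',
      '</selectedIonList><activation><cvParam cvRef="MS" ',
      'accession="MS:1000133" name="collision-induced dissociation" ',
      'value=""/></activation></precursor></precursorList>'), s$prec) else ""
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
      '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>',
      '<scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" ',
      'name="scan start time" value="%.4f" unitCvRef="UO" ',
      'unitAccession="UO:0000010" unitName="second"/></scan></scanList>%s',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" ',
      'accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" ',
      'unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" ',
      'accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" ',
      'unitCvRef="MS" unitAccession="MS:1000131" ',
      'unitName="number of detector counts"/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      index, id, length(s$mz), s$mslevel, s$rt, prec,
      nchar(b64mz), b64mz, nchar(b64i), b64i)
  }
  body <- paste(vapply(seq_along(specs), function(i) {
    one(i - 1L, i, specs[[i]])
  }, ""), collapse = "\n")
  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2"><cv id="MS" fullName="PSI MS Ontology" ',
    'URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" ',
    'URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/></cvList>\n',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" ',
    'name="MSn spectrum" value=""/></fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0.1">',
    '<cvParam cvRef="MS" accession="MS:1000799" ',
    'name="custom unreleased software tool" value="test"/></software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" ',
    'accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">\n%s\n',
    '</spectrumList></run></mzML>'), length(specs), body)
  writeLines(xml, path, useBytes = TRUE)
  path
}
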