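# Frozen maximum-ASA reference values. Regenerate with
# compute_max_asa_table() if the ASA settings or radii tables change; a
# regression test asserts the shipped constants match a recomputation.

#' Maximum backbone and side-chain ASA per residue type
#'
#' Reference areas (Angstrom^2) used to scale residue-level ASA into
#' relative exposure: the backbone (N, CA, C, O) and side-chain ASA of the
#' central residue in an idealized fully extended ALA-X-ALA tripeptide,
#' computed with [compute_asa()] at probe 1.4 and 960 sphere points (see
#' [compute_max_asa_table()]). Frozen as constants for reproducibility.
#'
#' @format Data.frame with columns `resname`, `max_bb`, `max_sc`.
#' @export
max_asa_table <- local({
  v <- c(
    "ALA", 46.8972, 55.2880,
    "ARG", 45.7775, 184.5210,
    "ASN", 45.3576, 96.6592,
    "ASP", 45.3576, 87.8975,
    "CYS", 45.9175, 81.3480,
    "GLN", 45.7775, 126.4938,
    "GLU", 45.7775, 119.5012,
    "GLY", 71.0526, 0.0000,
    "HIS", 44.1071, 131.9620,
    "ILE", 39.1984, 127.6524,
    "LEU", 44.9932, 113.9354,
    "LYS", 45.7775, 150.7202,
    "MET", 45.7775, 139.4474,
    "PHE", 43.4350, 151.9681,
    "PRO", 40.3415, 90.1405,
    "SER", 46.6173, 63.0468,
    "THR", 40.1782, 92.0211,
    "TRP", 42.4367, 195.7893,
    "TYR", 43.4350, 164.8872,
    "VAL", 39.1984, 103.8575
  )
  m <- matrix(v, ncol = 3, byrow = TRUE)
  data.frame(resname = m[, 1], max_bb = as.numeric(m[, 2]),
             max_sc = as.numeric(m[, 3]), stringsAsFactors = FALSE)
})
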