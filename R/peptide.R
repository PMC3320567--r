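#' Define a pY-anchored phosphopeptide window
#'
#' SH2-domain ligands are described here as 9-residue windows running from
#' pY-1 to pY+7, anchored on the phosphotyrosine. The sequence uses one-letter
#' codes with a lower-case `y` marking the phosphotyrosine at the second
#' position (e.g. `"GyRPQNVLT"` for a peptide numbered 113-121 with pY at
#' 114); the three-letter code of the `y` position is `PTR`.
#'
#' @param py_number Author sequence number of the phosphotyrosine.
#' @param sequence 9-character one-letter sequence with `y` at position 2.
#' @param chain Chain identifier the peptide lives on (default `"B"`).
#' @return A `peptide_def` object: a list with `py_number`, `start_number`,
#'   `end_number`, `sequence`, `chain` and a `residues` tibble (`resnum`,
#'   `offset`, `aa`, `resname`, `region`).
#' @export
#' @examples
#' make_peptide(114, "GyRPQNVLT")
#' make_peptide(127, "GyTTFEDAR")
make_peptide <- function(py_number, sequence, chain = "B") {
  if (!is.character(sequence) || length(sequence) != 1 ||
      nchar(sequence) != 9) {
    abort("peptide sequence must be a single 9-character string (pY-1 .. pY+7)")
  }
  aa <- strsplit(sequence, "")[[1]]
  if (aa[2] != "y") {
    abort("position 2 of the peptide sequence must be the phosphotyrosine marker 'y'")
  }
  py_number <- as.integer(py_number)
  offsets <- -1:7
  resnum <- py_number + offsets
  resname <- .aa1_to_3(aa)
  residues <- tibble(resnum = resnum, offset = offsets, aa = aa,
                     resname = resname,
                     region = region_of(offsets))
  structure(list(py_number = py_number,
                 start_number = py_number - 1L,
                 end_number = py_number + 7L,
                 sequence = sequence, chain = chain,
                 residues = residues),
            class = "peptide_def")
}

.aa_codes <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
               y = "PTR")

.aa1_to_3 <- function(aa) {
  out <- .aa_codes[aa]
  if (any(is.na(out))) {
    abort(paste0("unknown one-letter residue code(s): ",
                 paste(unique(aa[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

.aa3_to_1 <- function(resname) {
  rev_map <- setNames(names(.aa_codes), .aa_codes)
  out <- rev_map[resname]
  if (any(is.na(out))) {
    abort(paste0("no one-letter code for residue(s): ",
                 paste(unique(resname[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

#' pY offset of an absolute residue number
#'
#' @param peptide A [make_peptide()] definition.
#' @param residue_number Absolute residue number(s) within the window.
#' @return Integer offset(s) from the phosphotyrosine (-1 .. +7).
#' @export
#' @examples
#' tip114 <- make_peptide(114, "GyRPQNVLT")
#' offset_of(tip114, 117)  # pY+3
offset_of <- function(peptide, residue_number) {
  stopifnot(inherits(peptide, "peptide_def"))
  residue_number <- as.integer(residue_number)
  out <- residue_number - peptide$py_number
  bad <- residue_number < peptide$start_number |
    residue_number > peptide$end_number
  if (any(bad)) {
    abort(paste0("residue number(s) outside peptide window ",
                 peptide$start_number, "-", peptide$end_number, ": ",
                 paste(residue_number[bad], collapse = ", ")))
  }
  out
}

#' Interface region of a pY offset
#'
#' The SH2 interface is dissected into three regions by ligand position:
#' region I is the phosphotyrosine and pY+1; region II is pY+2 and pY+3;
#' region III is pY+4 through pY+8. The N-terminal flanking residue pY-1 is
#' outside this scheme and reports as `"flank"`.
#'
#' @param offset Integer pY offset(s) in -1 .. +8.
#' @return Character vector of `"flank"`, `"I"`, `"II"`, `"III"`.
#' @export
#' @examples
#' region_of(c(-1, 0, 3, 7))
region_of <- function(offset) {
  offset <- as.integer(offset)
  if (any(offset < -1 | offset > 8)) {
    abort("pY offset must be within -1 .. +8")
  }
  dplyr::case_when(
    offset == -1 ~ "flank",
    offset <= 1 ~ "I",
    offset <= 3 ~ "II",
    TRUE ~ "III"
  )
}

#' @export
print.peptide_def <- function(x, ...) {
  cat(sprintf("<peptide_def> chain %s, residues %d-%d, pY at %d: %s\n",
              x$chain, x$start_number, x$end_number, x$py_number, x$sequence))
  invisible(x)
}

# Display label for a ligand residue, e.g. "pY114", "R115".
.ligand_label <- function(resname, resnum) {
  one <- .aa3_to_1(resname)
  ifelse(one == "y", paste0("pY", resnum), paste0(one, resnum))
}

# Display label for a receptor residue, e.g. "K591".
.receptor_label <- function(resname, resnum) {
  paste0(.aa3_to_1(resname), resnum)
}
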