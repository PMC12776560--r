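#' Read the C1' chain of an RNA from PDB text
#'
#' Extracts a single RNA chain from PDB-format coordinates, keeping one C1'
#' atom per residue. Both atom-name dialects (`C1'` and the legacy `C1*`)
#' are recognized. All other atoms are used only to establish which
#' residues exist: a residue present in the chain but lacking a C1' atom is
#' kept with missing coordinates (unsolved). `HETATM` records, waters and
#' chains without any C1' atom (e.g. protein partners) are ignored
#' entirely. For alternate locations the first encountered atom wins.
#'
#' @param pdb Path to a PDB file, or the PDB text itself (a string
#'   containing newlines, or a character vector of lines).
#' @param chain_id Chain to extract. May be omitted when exactly one chain
#'   carries C1' atoms; with several RNA chains present it is required.
#' @return A [coord_chain()].
#' @examples
#' txt <- write_c1_chain(coord_chain(1:3, c("A", "C", "G"),
#'                                   x = c(0, 5, 10), y = 0, z = 0))
#' read_c1_chain(txt)
#' @export
read_c1_chain <- function(pdb, chain_id = NULL) {
  lines <- pdb_lines(pdb)
  atom <- lines[startsWith(lines, "ATOM")]
  if (length(atom) == 0) abort_input("no ATOM records found in PDB input")
  fx <- function(l, a, b) substr(l, a, b)
  name <- trimws(fx(atom, 13, 16))
  altloc <- fx(atom, 17, 17)
  resname <- trimws(fx(atom, 18, 20))
  chain <- fx(atom, 22, 22)
  resseq <- suppressWarnings(as.integer(trimws(fx(atom, 23, 26))))
  icode <- gsub(" ", "", fx(atom, 27, 27))
  is_c1 <- name %in% c("C1'", "C1*")
  rna_chains <- unique(chain[is_c1])
  if (length(rna_chains) == 0) abort_input("no C1' atoms found in PDB input")
  if (is.null(chain_id)) {
    if (length(rna_chains) > 1) {
      abort_input(paste0("multiple chains carry C1' atoms (",
                         paste(rna_chains, collapse = ", "),
                         "); supply `chain_id`"))
    }
    chain_id <- rna_chains
  }
  if (!chain_id %in% rna_chains) {
    abort_input(paste0("chain '", chain_id, "' has no C1' atoms"))
  }
  sel <- chain == chain_id
  key <- paste0(resseq[sel], icode[sel])
  first <- !duplicated(key)
  res_key <- key[first]
  res_id <- resseq[sel][first]
  res_ins <- icode[sel][first]
  res_code <- vapply(resname[sel][first], normalize_code, character(1))
  # first C1' per residue (file order covers the altloc keep-first rule)
  c1 <- sel & is_c1
  c1key <- paste0(resseq[c1], icode[c1])
  c1first <- !duplicated(c1key)
  xyz <- matrix(NA_real_, length(res_key), 3)
  hit <- match(c1key[c1first], res_key)
  coords <- cbind(as.numeric(fx(atom[c1], 31, 38)[c1first]),
                  as.numeric(fx(atom[c1], 39, 46)[c1first]),
                  as.numeric(fx(atom[c1], 47, 54)[c1first]))
  xyz[hit, ] <- coords
  coord_chain(seq_id = res_id, code = res_code,
              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
              chain_id = chain_id, ins = res_ins)
}

# One-letter nucleotide code from a PDB residue name; anything outside the
# A/C/G/U alphabet (modified residues) maps to N.
normalize_code <- function(resname) {
  code <- toupper(resname)
  if (nchar(code) > 1) code <- substr(code, nchar(code), nchar(code))
  if (!code %in% c("A", "C", "G", "U")) code <- "N"
  code
}

pdb_lines <- function(pdb) {
  if (length(pdb) > 1) return(pdb)
  if (grepl("\n", pdb, fixed = TRUE)) {
    strsplit(pdb, "\n", fixed = TRUE)[[1]]
  } else {
    if (!file.exists(pdb)) abort_input(paste0("PDB file not found: ", pdb))
    readLines(pdb, warn = FALSE)
  }
}

#' Write a C1' chain as minimal PDB text
#'
#' Emits one `ATOM` record per solved residue (atom name `C1'`, fixed-width
#' PDB columns, coordinates rounded to 3 decimals). The output round-trips
#' through [read_c1_chain()] losslessly apart from that rounding.
#'
#' @param chain A [coord_chain()].
#' @param path Optional file to write to; the text is returned invisibly in
#'   that case.
#' @return PDB text as a single string.
#' @export
write_c1_chain <- function(chain, path = NULL) {
  if (chain_length(chain) == 0) abort_input("cannot write an empty chain")
  solved <- which(!is.na(chain$x))
  recs <- sprintf("ATOM  %5d  C1' %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
                  seq_along(solved),
                  chain$code[solved],
                  substr(chain_id(chain), 1, 1),
                  chain$seq_id[solved],
                  ifelse(chain$ins[solved] == "", " ", chain$ins[solved]),
                  chain$x[solved], chain$y[solved], chain$z[solved])
  txt <- paste0(paste(c(recs, "END"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
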