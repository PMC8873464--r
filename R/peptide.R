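## Peptide quality control: average mass of modified peptides and
## Beer-Lambert concentration from absorbance.

## IUPAC average residue masses (Da), 2-decimal convention.
.residue_avg_mass <- c(
  G = 57.05, A = 71.08, S = 87.08, P = 97.12, V = 99.13,
  T = 101.10, C = 103.14, L = 113.16, I = 113.16, N = 114.10,
  D = 115.09, Q = 128.13, K = 128.17, E = 129.12, M = 131.19,
  H = 137.14, F = 147.18, R = 156.19, Y = 163.18, W = 186.21
)

.mass_water <- 18.015
.mass_amide_delta <- 0.984   # C-terminal OH -> NH2
.mass_disulfide_delta <- 2.016  # loss of 2 H per bridge

#' Islet amyloid polypeptide sequences
#'
#' One-letter sequences of the 37-residue wild-type peptide and its Ser20->Gly
#' natural variant.  Both carry a Cys2-Cys7 disulfide and an amidated
#' C-terminus in their mature form.
#'
#' @return Named character vector with elements `wt` and `S20G`.
#' @export
hiapp_sequences <- function() {
  wt <- "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY"
  s20g <- paste0(substr(wt, 1, 19), "G", substr(wt, 21, 37))
  c(wt = wt, S20G = s20g)
}

#' Average mass of a (modified) peptide
#'
#' Sum of standard average residue masses plus one water, minus 0.984 Da for
#' a C-terminal amide (OH -> NH2) and 2.016 Da per disulfide bridge (loss of
#' two hydrogens).  Average (not monoisotopic) masses are used, matching the
#' convention of deconvolved ESI-MS "expected" masses of peptides this size.
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param c_terminal_amide Is the C-terminus amidated?
#' @param disulfide_pairs List of residue-index pairs (1-based) forming
#'   disulfide bridges; both indices must be Cys.
#' @return Average mass in Da, rounded to 1 decimal.
#' @examples
#' peptide_average_mass(hiapp_sequences()["wt"], c_terminal_amide = TRUE,
#'                      disulfide_pairs = list(c(2, 7)))  # 3903.3
#' @export
peptide_average_mass <- function(sequence, c_terminal_amide = FALSE,
                                 disulfide_pairs = list()) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) == 0) {
    abort("sequence must be a single non-empty string",
          class = "amylokin_invalid_input")
  }
  aa <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(aa, names(.residue_avg_mass))
  if (length(unknown)) {
    abort(paste0("unknown residue letter(s): ", paste(unknown, collapse = ", ")),
          class = "amylokin_invalid_input")
  }
  for (pair in disulfide_pairs) {
    if (length(pair) != 2 || any(pair < 1) || any(pair > length(aa)) ||
        any(aa[pair] != "C")) {
      abort("disulfide pairs must index Cys residues",
            class = "amylokin_invalid_input")
    }
  }
  mass <- sum(.residue_avg_mass[aa]) + .mass_water -
    (if (c_terminal_amide) .mass_amide_delta else 0) -
    length(disulfide_pairs) * .mass_disulfide_delta
  round(mass, 1)
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' `C = A / (epsilon * path)`.  The default extinction coefficient,
#' 1620 M^-1 cm^-1 at 280 nm, is that of a single-tyrosine, single-disulfide
#' peptide.
#'
#' @param A Absorbance (dimensionless, >= 0).
#' @param epsilon Molar extinction coefficient (M^-1 cm^-1).
#' @param path Path length (cm).
#' @return Concentration in M.
#' @examples
#' concentration_from_absorbance(0.162) * 1e6  # 100 uM
#' @export
concentration_from_absorbance <- function(A, epsilon = 1620, path = 1) {
  if (any(A < 0)) abort("absorbance must be >= 0", class = "amylokin_invalid_input")
  if (epsilon <= 0 || path <= 0) {
    abort("epsilon and path must be > 0", class = "amylokin_invalid_input")
  }
  A / (epsilon * path)
}

#' Read a single-record FASTA peptide sequence
#'
#' FASTA carries no modification notation, so the amide / disulfide state is
#' supplied separately to [peptide_average_mass()].
#'
#' @param path Path to a FASTA file with exactly one record.
#' @return The sequence as a single upper-case string (named by the record id).
#' @export
read_peptide_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) != 1L) {
    abort("expected exactly one FASTA record", class = "amylokin_invalid_input")
  }
  setNames(toupper(as.character(seqs[[1]])), names(seqs)[1])
}
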