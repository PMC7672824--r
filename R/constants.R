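#' Amino-acid alphabets
#'
#' `AA_CANONICAL` is the alphabetical one-letter ordering used to lay out
#' gapped-dipeptide feature vectors. `AA_PSIBLAST` is the column order of
#' the 20 log-odds columns as printed in PSI-BLAST ASCII PSSM output.
#'
#' @format Character vectors of length 20.
#' @export
AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @rdname AA_CANONICAL
#' @export
AA_PSIBLAST <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Recommended PSI-BLAST parameters for PSSM generation
#'
#' PSSMs are consumed as files, never generated by this package. Users who
#' produce their own profiles externally can use this fast (insensitive)
#' PSI-BLAST setting, which trades search sensitivity for runtime while
#' retaining enough evolutionary signal for gapped-dipeptide features.
#'
#' @format A single character string of `psiblast` command-line flags.
#' @export
PSIBLAST_PARAMS <-
  "-matrix BLOSUM80 -evalue 1e-5 -gapopen 9 -gapextend 2 -threshold 999 -seg yes -soft_masking true -num_iterations 2"

# Namespace labels: OBO long names -> three-letter ontology codes.
GO_NAMESPACE_MAP <- c(
  biological_process = "BPO",
  cellular_component = "CCO",
  molecular_function = "MFO",
  BPO = "BPO", CCO = "CCO", MFO = "MFO"
)
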