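#' Y-STR locus panels
#'
#' The Yfiler panel types 17 Y-STR values. Haplotype analysis uses a 15-locus
#' profile: the multi-copy loci DYS385a/b are excluded (copies cannot be
#' assigned to a chromosome arm, so step distances are ill-defined), and
#' DYS389II, which physically contains DYS389I, is replaced by
#' DYS389b = DYS389II - DYS389I so that a single repeat change never counts
#' twice. DYS19 occasionally occurs duplicated (a second copy, DYS19-2);
#' such haplotypes are flagged and DYS19 is dropped from pairwise comparisons
#' involving them.
#'
#' @format Character vectors of locus names.
#' @name ystr_loci
NULL

#' @rdname ystr_loci
#' @export
YSTR_RAW_LOCI <- c(
  "DYS389I", "DYS389II", "DYS390", "DYS456", "DYS19", "DYS19_2",
  "DYS385a", "DYS385b", "DYS458", "DYS437", "DYS438", "DYS448",
  "GATA_H4", "DYS391", "DYS392", "DYS393", "DYS439", "DYS635"
)

#' @rdname ystr_loci
#' @export
YSTR_15_LOCI <- c(
  "DYS389I", "DYS389b", "DYS390", "DYS456", "DYS19", "DYS458", "DYS437",
  "DYS438", "DYS448", "GATA_H4", "DYS391", "DYS392", "DYS393", "DYS439",
  "DYS635"
)

# raw loci that must be present to derive a 15-locus profile
YSTR_REQUIRED_RAW <- setdiff(YSTR_RAW_LOCI, c("DYS19_2", "DYS385a", "DYS385b"))

#' The 35 Y-SNP markers of the genotyping panel
#' @format Character vector of marker names.
#' @export
YSNP_MARKERS <- c(
  "M217", "M48", "M174", "M35.1", "M78", "M123", "M285", "P15", "P303",
  "M406", "M69", "M170", "M267", "P58", "M172", "M47", "M67", "M12", "M92",
  "M20", "LLY22g", "M128", "M178", "M119", "P31", "M122", "P201", "M134",
  "M242", "M198", "M458", "M343", "M269", "M124", "M70"
)

# allele plausibility bounds for repeat counts
ALLELE_MIN <- 5L
ALLELE_MAX <- 60L
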