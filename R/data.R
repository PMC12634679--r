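# Shipped reference data: the hydration-free-energy benchmark table and the
# B1 domain sequence of streptococcal protein G.

#' Hydration free energies of amino-acid side-chain mimics
#'
#' Experimental and FEP-calculated hydration free energies (kcal mol^-1) of
#' the 12 neutral, non-glycine/proline side-chain mimics relative to methane
#' (the alanine side-chain mimic), the classic benchmark for validating
#' alchemical side-chain transformations: each value is the free-energy cost
#' of transforming the mimic into methane, compared between water and vacuum
#' spheres. Calculated values carry the SEM over 10 replica simulations.
#'
#' @param method which calculated column to expose as \code{ddg_calc}:
#'   "bar" (default) or "zwanzig".
#' @return a \linkS4class{BenchmarkTable} of 12 quantitative records.
#' @examples
#' figuresOfMerit(hydrationBenchmark())$tau
#' @export
hydrationBenchmark <- function(method = c("bar", "zwanzig")) {
  method <- match.arg(method)
  path <- system.file("extdata", "hydration_benchmark.csv",
                      package = "resFEP", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  calc <- if (method == "bar") d$ddg_bar else d$ddg_zwanzig
  sem <- if (method == "bar") d$sem_bar else d$sem_zwanzig
  assembleBenchmark(
    data.frame(id = d$amino_acid, ddg_exp = d$ddg_exp, ddg_calc = calc,
               sem = sem, qualitative = FALSE, stringsAsFactors = FALSE),
    dataset = paste0("hydration-", method))
}

#' Sequence of the B1 domain of streptococcal protein G
#'
#' The 56-residue domain used for domain-wide comprehensive mutagenesis
#' scans (1-letter code).
#'
#' @return character scalar of length-56 sequence.
#' @export
gb1Sequence <- function()
  "MTYKLILNGKTLKGETTTEAVDAATAEKVFKQYANDNGVDGEWTYDDATKTFTVTE"
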