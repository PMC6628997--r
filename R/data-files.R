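#' Paths to the packaged clock coefficient files
#'
#' The package ships coefficient tables in the conventional published-clock
#' layout under `inst/extdata/`. These are *synthetic* stand-ins (random
#' probe ids and weights) that reproduce the structural facts of the real
#' placental clocks: the robust placental clock (RPC) has 558 CpGs, the
#' control placental clock (CPC) 546 with 199 CpGs shared with the RPC, the
#' refined RPC 395 CpGs all drawn from the RPC's set, and the fetal-sex
#' classifier 220 CpGs. They exercise file handling, prediction arithmetic
#' and set operations; their weights carry no biological meaning.
#'
#' @param name One of `"rpc"`, `"cpc"`, `"refined_rpc"`, `"sex_classifier"`.
#' @return Path to the installed CSV file.
#' @examples
#' rpc <- read_clock(clock_file("rpc"))
#' rpc$n_features  # 558
#' @export
clock_file <- function(name = c("rpc", "cpc", "refined_rpc", "sex_classifier")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_synthetic.csv"),
                      package = "plclock", mustWork = TRUE)
  path
}
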