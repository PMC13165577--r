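#!/usr/bin/env Rscript
# Command-line front end for the simulate / analyze / roundtrip pipeline.
#
#   Rscript scripts/coflow.R simulate --config run.yaml --out DIR
#   Rscript scripts/coflow.R analyze  --config run.yaml --tiff stack.tiff --out DIR
#   Rscript scripts/coflow.R roundtrip --config run.yaml --out DIR
#
# Flags: --seed overrides the config seed.

suppressMessages({
  library(optparse)
  library(coflowrheo)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "analyze", "roundtrip")) {
  cat("usage: coflow.R <simulate|analyze|roundtrip> --config FILE --out DIR [--tiff FILE] [--seed INT]\n")
  quit(status = 2)
}
mode <- args[1]

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", help = "YAML run configuration"),
  make_option("--out", type = "character", help = "output directory"),
  make_option("--tiff", type = "character", default = NULL,
              help = "input TIFF stack (analyze mode)"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the config seed")))
opt <- parse_args(parser, args = args[-1])
if (is.null(opt$config) || is.null(opt$out)) {
  cat("error: --config and --out are required\n"); quit(status = 2)
}

cfg <- tryCatch(read_run_config(opt$config), error = function(e) {
  cat("config error:", conditionMessage(e), "\n"); quit(status = 1)
})
if (!is.null(opt$seed)) {
  sections <- cfg$sections
  cfg <- run_config(geometry = sections$geometry, scenario = sections$scenario,
                    blood = sections$blood, render = sections$render,
                    analysis = sections$analysis, seed = opt$seed)
}

status <- tryCatch({
  if (mode == "simulate") {
    res <- run_simulate(cfg, opt$out)
    cat("dataset:", res$tiff, "\nmanifest:", res$manifest, "\n")
  } else if (mode == "analyze") {
    if (is.null(opt$tiff)) stop("analyze mode requires --tiff")
    run_analyze(cfg, opt$tiff, opt$out)
    cat("results in", opt$out, "\n")
  } else {
    rt <- run_roundtrip(cfg, opt$out)
    cat("roundtrip report:", file.path(opt$out, "roundtrip.json"), "\n")
    cat(sprintf("median |mu error|: %.2f%%, max |AI error|: %.4f\n",
                rt$aggregate$mu_median_abs_rel_err_pct,
                rt$aggregate$ai_max_abs_err))
  }
  0L
}, error = function(e) {
  cat("error:", conditionMessage(e), "\n")
  1L
})
quit(status = status)
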