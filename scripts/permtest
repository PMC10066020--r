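#!/usr/bin/env Rscript
# Thin command-line wrapper; all logic lives in the exactperm package.
suppressPackageStartupMessages(library(exactperm))
quit(status = run_cli(commandArgs(trailingOnly = TRUE)), save = "no")
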