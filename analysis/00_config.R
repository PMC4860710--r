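# Shared settings for the analysis scripts. Run every script from the
# repository root, e.g.  Rscript analysis/01_simulate.R
# All stages are deterministic under this seed; rerunning any script
# reproduces its tables byte for byte.

suppressMessages(library(methcap))

SEED <- 1
CFG <- sim_config(seed = SEED)
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

stamp <- paste0("methcap ", as.character(packageVersion("methcap")),
                " seed=", SEED)

# every script regenerates what it needs; the generator is fast and seeded
annotation <- function() generate_annotation(CFG)
methylation <- function(ann) simulate_methylation(CFG, ann)
expression_data <- function(ann, meth) simulate_expression(CFG, ann, meth)
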