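#!/usr/bin/env Rscript
# Stage 3: exhaustive maximum-parsimony inference, support and a-posteriori
# character mapping, validated end to end on simulated karyotype evolution.
#
# The published 7 x 55 basic data matrix is not distributed in machine-
# readable form, so the full seven-taxon pipeline is exercised on data
# simulated under the published study design: the rooted topology
# ((DEC,(DRO,DYO)),(TSA,(LSI,(PHA,PDI)))), an ancestral complement of 16
# conserved units (a PHA-like complement), and rearrangement events
# accumulated along the branches. Two experiments:
#
#   (a) a showcase run: one simulated dataset through the entire pipeline
#       (exhaustive search over all 945 topologies, 2000 bootstrap
#       replicates, Bremer decay by full enumeration, outgroup rooting,
#       apomorphy classification); report written to results/simulated_run/.
#   (b) a recovery study over 100 homoplasy-free simulations per event mix:
#       under the durable-marker mix (fusion + inversion) the generating
#       topology must be the unique MP tree in every clean run; under the
#       full mix (fission and translocation enabled) clean runs can be
#       non-identifying, and the achieved fraction is reported.
#
# If a transcription of the published matrix is installed at
# inst/extdata/published_character_matrix.nex it is analysed first.

suppressMessages({
  library(chromoclad)
  library(ape)
})

dir.create("results", showWarnings = FALSE)
outgroup <- c("DEC", "DRO", "DYO")
tree <- read.tree(
  text = "((DEC:1,(DRO:1,DYO:1):1):1,(TSA:1,(LSI:1,(PHA:1,PDI:1):1):1):1);")

## published matrix, when a transcription is available ----------------------
path <- published_matrix_path()
if (!is.na(path)) {
  cat("Analysing the published character matrix:\n")
  cm <- read_nexus_matrix(path)
  run <- run_chromosome_phylogeny(matrix = cm, outgroup = outgroup,
                                  n_bootstrap = 2000L, seed = 2015L)
  print(run)
  write_run_report(run, "results/published_run")
} else {
  cat("No machine-readable published matrix installed; running the\n")
  cat("simulation-validated pipeline only.\n\n")
}

## (a) showcase run ----------------------------------------------------------
sim <- simulate_karyotypes(sim_config(tree, ancestral_units = 16L,
                                      seed = 2015L,
                                      per_branch_events = 2L))
cat("Simulated dataset:\n")
print(sim)
run <- run_chromosome_phylogeny(matrix = sim$matrix, outgroup = outgroup,
                                n_bootstrap = 2000L, seed = 2015L)
print(run)
cat("\nRooted MP tree:", write.tree(run$rooted_tree), "\n")
cat("Clade support (bootstrap % / Bremer):\n")
for (i in seq_len(nrow(run$bremer))) {
  cat(sprintf("  %-28s %5.1f / %d\n", run$bremer$clade[i],
              support_for(run$bootstrap,
                          strsplit(run$bremer$clade[i], "+",
                                   fixed = TRUE)[[1L]]),
              run$bremer$bremer[i]))
}
print(run$root_report)
write_run_report(run, "results/simulated_run")
cat("Wrote results/simulated_run/\n\n")

## (b) recovery study --------------------------------------------------------
space <- topology_space(tree$tip.label)
truth <- unroot(tree)
recovery <- function(rates, label) {
  clean <- 0L; recovered <- 0L; seed <- 0L
  while (clean < 100L && seed < 5000L) {
    seed <- seed + 1L
    s <- simulate_karyotypes(sim_config(tree, rates = rates, seed = seed,
                                        per_branch_events = 2L))
    if (fitch_length(tree, s$matrix) != sum(char_min_steps(s$matrix))) next
    clean <- clean + 1L
    res <- exhaustive_search(s$matrix, space = space)
    stopifnot(res$ci == 1)
    if (length(res$mp_trees) == 1L &&
        dist.topo(unroot(res$mp_trees[[1L]]), truth) == 0) {
      recovered <- recovered + 1L
    }
  }
  cat(sprintf("  %-34s %3d / %3d clean runs recovered (tried %d seeds)\n",
              label, recovered, clean, seed))
  data.frame(event_mix = label, clean_runs = clean, recovered = recovered,
             seeds_tried = seed)
}
cat("Recovery of the generating topology (unique MP tree) on homoplasy-free runs:\n")
out <- rbind(
  recovery(c(fusion = 0.5, fission = 0, translocation = 0, inversion = 0.5),
           "fusion+inversion (durable)"),
  recovery(c(fusion = 0.3, fission = 0.3, translocation = 0.2,
             inversion = 0.2), "full mix (erasable markers)"))
write.table(out, "results/recovery_study.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/recovery_study.tsv\n")
cat("\nUnder the full mix, a fission or translocation below a marked branch\n")
cat("can erase an association, or re-read it as a marker of a nested clade,\n")
cat("without raising any character above its minimum steps -- such clean\n")
cat("runs are genuinely non-identifying, which is why the guarantee is\n")
cat("stated for the durable event mix only.\n")
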