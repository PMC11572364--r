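#!/usr/bin/env Rscript
# Build the ground-truthed synthetic data set used by the downstream
# analyses: a 31,099 bp circular chromosome with the published 34-feature
# layout, two microDNA circles (291 and 140 bp), planted terminal repeats,
# a tandem-array decoy and a NUMT copy in a 10 kb host, and paired-end
# read libraries. Everything is seeded; re-running reproduces the same
# bytes.
#
# Reads for the microDNA and host molecules are simulated at 100x, the
# depth at which the downstream circle-calling analysis operates; the main
# chromosome gets a lighter 25x library, which is plenty for its summary
# statistics and keeps the bundle small.

suppressPackageStartupMessages(library(mitosplit))
dir.create("results/simulation", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20240901, error_rate = 0.01)
message("simulating the published-layout genome ...")
sim <- simulate_genome(cfg)
sim <- plant_artifacts(sim)

for (id in names(sim$chromosomes)) {
  write_fasta(stats::setNames(sim$chromosomes[[id]]$sequence, id),
              file.path("results/simulation", paste0(id, ".fasta")))
}
for (id in names(sim$tables)) {
  write_gene_table(sim$tables[[id]],
                   file.path("results/simulation", paste0(id, "_genes.tsv")))
}

reads_md <- simulate_reads(sim$chromosomes[c("chrM2", "chrM3", "host")],
                           cfg, depth = 100)
write_fastq(reads_md, "results/simulation/microdna_host_R1.fastq.gz",
            "results/simulation/microdna_host_R2.fastq.gz")
reads_m1 <- simulate_reads(sim$chromosomes["chrM1"], cfg, depth = 25)
write_fastq(reads_m1, "results/simulation/chrM1_R1.fastq.gz",
            "results/simulation/chrM1_R2.fastq.gz")

truth <- list(
  seed = cfg$seed,
  chromosome_lengths = lapply(sim$chromosomes, `[[`, "length"),
  planted_repeats = sim$truth$repeats,
  tandem_decoy = sim$truth$tandem_decoys[c("unit_id", "unit_length",
                                           "copies", "host_pos")],
  decoy_contig = sim$truth$tandem_decoys$contig,
  numts = sim$truth$numts)
jsonlite::write_json(truth, "results/simulation/truth.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA,
                     dataframe = "rows")

message("wrote results/simulation/: ",
        paste(list.files("results/simulation"), collapse = ", "))
message("read pairs: microDNA/host ", length(reads_md$read1),
        ", chrM1 ", length(reads_m1$read1))
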