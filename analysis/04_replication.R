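#!/usr/bin/env Rscript

# Replication triage, twice over.
#
# First on the simulation: align the discovered lead SNPs to the
# simulated replication GWAS and partition them into replicated /
# intermediate / attenuated. Antagonistic leads carry a real trait-2
# effect and should replicate; any shared-signal stragglers should not.
#
# Second on the published worked example bundled with the package: four
# loci with opposite schizophrenia/PTSD effects, triaged against a
# trans-ancestry PTSD meta-analysis. The expected picture: one lead
# (rs62062288, the MAPT/CRHR1 locus) retains genome-wide significance,
# the other three attenuate (all P > 0.001).

suppressPackageStartupMessages({
  library(diffgwas)
  library(data.table)
})

diff <- read_tsv("results/diff_results.tsv.gz")
loci <- fread("results/candidate_loci.tsv")
rep <- read_tsv("results/sim/replication.tsv.gz")

leads <- merge(loci[, .(chrom = as.character(chrom), rsid = lead_rsid,
                        pos = lead_pos)],
               diff[, .(chrom = as.character(chrom), pos, rsid, a1, a2,
                        beta2)],
               by = c("chrom", "pos", "rsid"))
sim_triage <- prioritize(align_to_replication(leads, rep))
write_tsv(sim_triage, "results/replication_triage.tsv")
cat("Simulated-replication triage of discovered leads:\n")
print(sim_triage)

pub <- published_lead_snps()
rp <- published_replication()
pub_triage <- prioritize(align_to_replication(
  data.table(chrom = as.character(pub$CHR), pos = NA_integer_,
             rsid = pub$RSID, a1 = pub$A1, a2 = pub$A2,
             beta2 = pub$BETA_PTSD),
  data.table(rsid = rp$RSID, a1 = rp$A1, a2 = rp$A2, z = rp$Z, p = rp$P)))
write_tsv(pub_triage, "results/published_triage.tsv")
cat("\nPublished four-locus triage (trans-ancestry PTSD):\n")
print(pub_triage)
cat(sprintf("\n%s retains genome-wide significance; %d loci attenuated.\n",
            pub_triage[status == "replicated"]$rsid,
            sum(pub_triage$status == "attenuated")))
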