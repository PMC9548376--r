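#!/usr/bin/env Rscript
# Single-allele genotyping of the amplicon fixture: classify every allele
# against the reference, census the composition, and locate the
# frameshift-induced premature stop.

suppressMessages(library(fuccitrack))

amp <- example_amplicon()
ref <- readLines("results/data/amplicon_ref.txt")[1]
stopifnot(identical(ref, amp$ref))
alleles <- read_alleles("results/data/alleles.fa")
calls <- lapply(as.character(alleles), classify_allele, ref = ref,
                cut_site = amp$cut_site)
census <- allele_census(calls)
print(census)

# premature stop scan on one mutant allele: the engineered cassette puts
# the first novel in-frame stop 8 bp downstream of the inserted base
mut_seq <- as.character(alleles)[vapply(calls, function(x)
  x$class == "insertion", logical(1))][1]
stop_rep <- find_premature_stop(mut_seq, ref,
                                cds_frame_offset = amp$frame_offset,
                                edit_pos = amp$edit_pos)
print(stop_rep)

out <- list(n_total = census$n_total, n_wt = census$n_wt,
            n_mut = census$n_mut, p_value = census$p_value,
            consistent_heterozygous = census$consistent_heterozygous,
            premature_stop = list(found = stop_rep$found,
                                  distance_bp = stop_rep$distance_bp))
jsonlite::write_json(out, "results/genotype.json", auto_unbox = TRUE,
                     digits = NA)
message("report at results/genotype.json")
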