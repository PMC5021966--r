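#!/usr/bin/env Rscript
# Stage 3: free and bioavailable 25OHD from the binding-equilibrium model
# (trace-ligand linear solver; Ka_DBP = 7e8 L/mol, Ka_alb = 6e5 L/mol).

library(vitdmr)

co <- read_cohort_tsv("results/cohort_analysed.tsv")
co <- add_free_d_columns(co)
write_cohort_tsv(co, "results/cohort_with_free.tsv")

s <- summarize_cohort(co, c("total_25ohd", "free_25ohd",
                            "bioavailable_25ohd"))
cat("Total, free (pg/mL) and bioavailable (ng/mL) 25OHD:\n")
print(render_table1(s), row.names = FALSE)
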