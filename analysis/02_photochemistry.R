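#!/usr/bin/env Rscript
# Stage 2: excitation pressure over PSII. Computes per-fragment Qm from the
# daily dark/light yield pairs and the heated-minus-control adjustment dQm
# per holobiont. Expect a large dQm for the Cladocopium holobiont (~0.17)
# and a small one for the Durusdinium holobiont (~0.02).

library(holotherm)

a <- load_assay_set("results/assays")
qm <- compute_qm(pair_yields(a$pam))
dq <- compute_delta_qm(qm, a$design, pooling = "overall")
dq_daily <- compute_delta_qm(qm, a$design, pooling = "per_day")

readr::write_csv(qm, "results/qm.csv")
readr::write_csv(dq, "results/delta_qm.csv")
readr::write_csv(dq_daily, "results/delta_qm_daily.csv")

cat("Pooled PSII thermal adjustment (heated minus control Qm):\n")
print(as.data.frame(dq), digits = 3)
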