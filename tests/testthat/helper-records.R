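# Randomized but seeded generic-measurement records for round-trip tests.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    kind <- sample(c("met", "prot", "trans", "od"), n, replace = TRUE)
    id <- character(n)
    unit <- character(n)
    id[kind == "met"] <- paste0("CID:", sample(100:99999,
                                               sum(kind == "met"), TRUE))
    unit[kind == "met"] <- sample(c("mg/L", "mM"), sum(kind == "met"), TRUE)
    id[kind == "prot"] <- paste0("P", sample(10000:99999,
                                             sum(kind == "prot"), TRUE))
    unit[kind == "prot"] <- "proteins/cell"
    id[kind == "trans"] <- paste0("b", sample(1000:4999,
                                              sum(kind == "trans"), TRUE))
    unit[kind == "trans"] <- "FPKM"
    id[kind == "od"] <- "OD"
    unit[kind == "od"] <- ""
    edd_records(
      line_name = sample(c("WT", paste0("BE", 1:20)), n, TRUE),
      measurement_id = id,
      time = round(stats::runif(n, 0, 24), 3),
      value = round(stats::runif(n, 0, 50), 6),
      unit = unit)
  })
}
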