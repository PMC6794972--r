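# build a noiseless summary series from a generating trajectory
series_from_params <- function(params, days = 1:7, sds = rep(1, length(days)),
                               n = 7, paste = "toy", condition = "with_saliva",
                               time_origin = 0) {
  occlusion_series(paste, condition, days,
                   logistic_solution(days - time_origin, params), sds, n)
}

# the six published summary cells, keyed as in occlusion_table1()
fixture_keys <- c("EB@TiO2 / without_saliva", "EB@TiO2 / with_saliva",
                  "Colgate Pro-relief / without_saliva",
                  "Colgate Pro-relief / with_saliva",
                  "Sensodyne repair / without_saliva",
                  "Sensodyne repair / with_saliva")

# generating truth matching the published design: published rates with the
# trajectory anchored at each group's day-1 mean (model time 0 = day 1)
fixture_truth <- function() {
  tab <- occlusion_table1()
  pr <- published_rates()
  x0 <- vapply(fixture_keys, function(k) tab[[k]]$means[1], numeric(1))
  info <- do.call(rbind, lapply(tab[fixture_keys], function(s)
    data.frame(paste = s$paste, condition = s$condition,
               stringsAsFactors = FALSE)))
  truth <- merge(info, pr, by = c("paste", "condition"), sort = FALSE)
  truth$K <- 100
  truth$x0 <- x0[match(paste(truth$paste, truth$condition, sep = " / "),
                       fixture_keys)]
  truth
}
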