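# Builders for hand-written vital-sample streams and cached reference runs.

make_samples <- function(etco2 = 7, spo2 = 98, ori = 0.2,
                         times = seq_along(etco2), hold = FALSE, valid = TRUE) {
  n <- max(lengths(list(etco2, spo2, ori, times)))
  tibble::tibble(
    timestamp = rep_len(times, n),
    etco2 = rep_len(etco2, n),
    spo2 = rep_len(spo2, n),
    ori = rep_len(ori, n),
    hold = rep_len(hold, n),
    valid = rep_len(valid, n)
  )
}

controller_input <- function(etco2_avg = 7, spo2_avg = 98, ori_avg = 0.2,
                             breath_hold = FALSE, stale = FALSE) {
  tibble::tibble(
    etco2_avg = etco2_avg, spo2_avg = spo2_avg, ori_avg = ori_avg,
    breath_hold = breath_hold, stale = stale
  )
}

# the noise-free default staircase run, computed once per test session
.run_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.run_cache$log)) {
    .run_cache$log <- run_protocol(seed = 1, noise = FALSE)
  }
  .run_cache$log
}
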