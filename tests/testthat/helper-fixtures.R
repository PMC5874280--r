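# Shared fixture builders. All randomness is seeded by the caller or inside
# generate_station(); nothing here touches the global RNG stream.

swiss_geometry <- function() {
  site_geometry(47.0, 7.5, standard_meridian = 15, elevation = 450)
}

# Small contiguous daily series with mild day-to-day variation.
mild_daily <- function(n = 10, tn = 10, tx = 22, jitter = 0, seed = 1) {
  d <- data.frame(date = as.Date("2003-06-01") + seq_len(n) - 1,
                  tmin = rep_len(tn, n), tmax = rep_len(tx, n))
  if (jitter > 0) {
    set.seed(seed)
    d$tmin <- d$tmin + runif(n, -jitter, jitter)
    d$tmax <- d$tmax + runif(n, -jitter, jitter)
  }
  d
}

# Noise-free clear-sky synthetic station: hourly record is exactly the model
# output at the generic parameter triple.
clean_station <- function(years = 1, seed = 11, ...) {
  generate_station(synthetic_config(years = years, hourly_noise_sd = 0,
                                    overcast_fraction = 0, seed = seed, ...))
}
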