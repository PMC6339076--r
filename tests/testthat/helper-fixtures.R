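# Sensor-table fixtures (two 10-row, 3-variable series) and the univariate
# worked example, built in code so every test can use them without touching
# disk.  The same tables ship as CSV under inst/extdata for the IO tests.

sensor_S <- function() {
  multivariate_series(
    list(temperature = c(35, 39, 36, 35, 37, 36, 38, 35, 38, 36),
         humidity = c(92, 82, 87, 91, 85, 87, 83, 90, 82, 86),
         soil_moisture = c(780, 778, 776, 774, 772, 772, 770, 767, 762, 756)),
    id = "S")
}

sensor_T <- function() {
  multivariate_series(
    list(temperature = c(37, 35, 36, 38, 35, 37, 38, 35, 38, 36),
         humidity = c(85, 92, 87, 84, 91, 85, 83, 90, 81, 86),
         soil_moisture = c(782, 780, 776, 775, 774, 772, 770, 767, 762, 756)),
    id = "T")
}

chars <- function(x) strsplit(x, "")[[1]]

worked_S <- function() chars("AEBACFDADB")
worked_T <- function() chars("CABDACDADB")

rand_seq <- function(len, alphabet_size = 4) {
  sample(LETTERS[seq_len(alphabet_size)], len, replace = TRUE)
}
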