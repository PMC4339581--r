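# Locate the deposited SIM feature dataset (MAT v5), if the user has placed
# it in the package. It is not redistributed here; see the README for the
# drop-in locations.
s1_dataset_path <- function() {
  candidates <- c(
    system.file("extdata", "s1_dataset.mat", package = "simcadx"),
    file.path("s1_dataset.mat")
  )
  candidates <- candidates[nzchar(candidates) & file.exists(candidates)]
  if (length(candidates)) candidates[[1L]] else ""
}
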