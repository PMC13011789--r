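# Shared fixtures, built once per test run.  The working grid is 46 x 55 x 46
# at 4 mm isotropic: the same geometry as the canonical 2 mm space at half
# resolution, which keeps template construction and registration fast while
# exercising identical code paths.

.fixture_env <- new.env(parent = emptyenv())

test_atlas <- function() {
  if (is.null(.fixture_env$atlas))
    .fixture_env$atlas <- build_synthetic_atlas(shape = c(46, 55, 46),
                                                voxel_size_mm = 4)
  .fixture_env$atlas
}

test_bank <- function() {
  if (is.null(.fixture_env$bank))
    .fixture_env$bank <- build_template_bank(test_atlas())
  .fixture_env$bank
}

# A minimal long-format SBR table.
make_sbr_table <- function(subject, tracer, value, region = "striatum",
                           side = "bilateral", session_years = 0,
                           age = 65, sex = 0) {
  data.frame(subject = subject, tracer = tracer,
             session_years = session_years, age = age, sex = sex,
             region = region, side = side, value = value,
             stringsAsFactors = FALSE)
}

# Voxel-count weights of the test atlas's putamen/striatum composites, so
# tabular truth matches image-rendered composites.
atlas_composite_weights <- function(atlas) {
  counts <- centamine:::atlas_voxel_counts(atlas)
  n_of <- function(r) sum(counts[as.character(
    centamine:::region_codes(atlas, r, "bilateral"))])
  n_pre <- n_of("pre_commissural_putamen")
  n_post <- n_of("post_commissural_putamen")
  n_caud <- n_of("caudate")
  list(w_pre = n_pre / (n_pre + n_post),
       w_caud = n_caud / (n_caud + n_pre + n_post))
}
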