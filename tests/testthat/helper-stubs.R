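# minimal stand-in model with predictions a fixed function of the
# environment table; exercises ensemble arithmetic exactly
stub_model <- function(cv, f, pset = predictor_sets()$set1) {
  structure(list(algorithm = "stub", predictor_set = pset, fun = f,
                 cv_boyce = cv, seed = 1),
            class = c("stub_sdm", "fitted_sdm"))
}

predict.stub_sdm <- function(object, newdata, ...) {
  invstack:::clamp01(object$fun(newdata))
}
registerS3method("predict", "stub_sdm", predict.stub_sdm)

# one shared small pipeline run, reused by the pipeline and acceptance tests
pipeline_run <- function() {
  if (is.null(.fixtures$run)) {
    cfg <- run_config(seed = 5, shape = c(40, 40), n_species = 6,
                      niche_config = list(lambda = 300),
                      out_dir = file.path(tempdir(), "invstack-run"))
    .fixtures$run <- suppressWarnings(run_pipeline(cfg))
  }
  .fixtures$run
}
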