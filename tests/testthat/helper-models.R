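# Shared trained models for the pipeline and acceptance tests. Training is
# deterministic and cached so each model is built once per test run.
.study_cache <- new.env(parent = emptyenv())

cached_model <- function(key, builder) {
  if (is.null(.study_cache[[key]])) assign(key, builder(), .study_cache)
  get(key, .study_cache)
}

ellipse_study_model <- function() cached_model("ellipse5", function()
  train_on_rotations(study_ellipse_family(), study_dbn_config("standard"),
                     seed = 42))

single_ellipse_model <- function() cached_model("ellipse1", function()
  train_on_rotations(list(make_ellipse(axes = c(20, 12), seed = 1)),
                     study_dbn_config("light"), seed = 42))

blob_study_model <- function() cached_model("blob", function()
  train_on_rotations(study_blob_family(), study_dbn_config("light"),
                     seed = 43))

fish_dbn_config <- function() study_dbn_config("fish")

fish_study_model <- function() cached_model("fish", function()
  train_on_rotations(study_fish_family(), fish_dbn_config(), seed = 44))

# A deliberately tiny model for interface/error-path tests.
tiny_model <- function() cached_model("tiny", function() {
  img <- make_ellipse(axes = c(12, 8), seed = 5)
  cfg <- dbn_config(n_hidden1 = 20, n_hidden2 = 15, epochs1 = 3,
                    epochs2 = 5, gibbs_iters = 20)
  train_dbn(list(img$image), list(img$truth), cfg, seed = 1)
})

tiny_dbn_cfg <- function() dbn_config(n_hidden1 = 20, n_hidden2 = 15,
                                      epochs1 = 3, epochs2 = 5,
                                      gibbs_iters = 20)
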