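# Shared fixtures. Expensive objects (the pretrained fixture encoder) are
# built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# three chi-rich fixture peptides used for encoder pretraining
fixture_peptides <- function() {
  cached("peptides", list(
    make_peptide("GALSKYEWTNDQ", "alpha"),
    make_peptide("MKVLFRHCIPST", "extended"),
    make_peptide("ADEFGHIKLMNW", "alpha")
  ))
}

# the desk-scale pretraining run: 3 peptides x 50 perturbations, 30 epochs
fixture_encoder_run <- function() {
  cached("encoder_run", {
    set.seed(11)
    samples <- make_perturbation_dataset(fixture_peptides(), 50)
    prep <- prepare_encoder_samples(samples)
    state <- train_encoder(prep, encoder_config(head_dim = 8L, epochs = 30L,
                                                seed = 1L))
    list(samples = samples, state = state)
  })
}

# a small trained encoder for feature-level tests (cheap)
tiny_encoder <- function() {
  cached("tiny_encoder", {
    set.seed(21)
    samples <- make_perturbation_dataset(list(make_peptide("GALSKY", "alpha")), 6)
    train_encoder(samples, encoder_config(head_dim = 3L, mlp_hidden = c(8L, 4L),
                                          epochs = 2L, seed = 3L))
  })
}

random_rotate_structure <- function(structure, seed) {
  transform_structure(structure, function(xyz) {
    out <- gatddg:::random_rigid_transform(xyz, rng_seed = seed)
    out
  })
}
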