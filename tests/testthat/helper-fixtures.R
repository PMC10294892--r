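# Shared fixtures: all built in code, no stored binaries.

# Uniform linear-elastic material field for an arbitrary mesh.
lin_mats <- function(mesh, E = 100, nu = 0.3) {
  material_field(
    tets = tibble::tibble(element = seq_len(nrow(mesh$tets)),
                          label = "cancellous", family = "linear",
                          rho = NA_real_, E = E, nu = nu),
    membranes = tibble::tibble(element = seq_len(nrow(mesh$tris)),
                               E = rep(E, nrow(mesh$tris)),
                               nu = rep(nu, nrow(mesh$tris))))
}

# All-Mooney-Rivlin material field.
mr_mats <- function(mesh) {
  material_field(
    tets = tibble::tibble(element = seq_len(nrow(mesh$tets)),
                          label = "cartilage_pubic", family = "mooney_rivlin",
                          rho = NA_real_, E = NA_real_, nu = NA_real_),
    membranes = tibble::tibble(element = integer(), E = double(), nu = double()))
}

# Phantom materials with cartilage forced linear (makes the whole model
# linear so exact load-scaling invariants hold).
all_linear_phantom_mats <- function(phantom, ct, E_cart = 50) {
  mats <- assign_materials(phantom$mesh, ct)
  cart <- mats$tets$family %in% c("mooney_rivlin", "cartilage")
  mats$tets$family[cart] <- "linear"
  mats$tets$E[cart] <- E_cart
  mats$tets$nu[cart] <- 0.2
  mats
}

# Small deterministic phantom shared across tests (built once per run).
test_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_pelvis_phantom(phantom_spec(block_resolution = 2))
    cache
  }
})

test_ct <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- rasterize_ct(test_phantom())
    cache
  }
})

random_deformation_gradient <- function(scale = 0.05) {
  repeat {
    F_ <- diag(3) + matrix(stats::rnorm(9, 0, scale), 3, 3)
    if (det(F_) > 0.8 && det(F_) < 1.2) return(F_)
  }
}

standing_bcs <- function() {
  list(boundary_condition("femur_fix", c("x", "y", "z")),
       boundary_condition("vertebra_guide", c("x", "z")))
}
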