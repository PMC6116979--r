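# shared fixtures: small meshes and states built in code at test time

small_disc <- function(n_rings = 6, n_sectors = 12, with_profile = TRUE) {
  disc <- make_disc(n_rings = n_rings, n_sectors = n_sectors)
  if (with_profile) disc$mesh <- make_stimulus_profile(disc$mesh)
  disc
}

uniform_column <- function(bvtv = 0.3, nz = 10,
                           params = default_config()$bone) {
  bone <- make_vertebra(nx = 3, ny = 3, nz = nz, voxel = 2,
                        shell_bvtv = bvtv, core_mean = bvtv, core_sd = 0,
                        seed = 1, params = params)
  bone$bvtv[] <- bvtv
  bone
}

# activity-result list with identical fields for every program activity
uniform_activities <- function(program, eps_dev, v_f = 0) {
  res <- lapply(program$activities, function(a)
    structure(list(eps_dev = eps_dev, v_f = rep_len(v_f, length(eps_dev)),
                   sed = 0 * eps_dev), class = "activity_result"))
  names(res) <- names(program$activities)
  res
}
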