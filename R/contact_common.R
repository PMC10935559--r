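# Contact-episode bookkeeping shared by both collision backends. An episode
# starts when a patch first appears and ends at separation; delta_dot0 (the
# normal approach rate at the first detecting step) is latched once per
# episode and held until separation.

#' Create a contact-episode state
#'
#' @return environment tracking per-patch episodes; pass to [mesh_contacts()]
#'   or [sphere_surface_contact()].
#' @export
contact_episodes <- function() {
  e <- new.env(parent = emptyenv())
  e$active <- list()   # patch id (character) -> list(delta_dot0, t0)
  e$log <- list()      # events: dislocation-candidate domain exits etc.
  e
}

episode_delta_dot0 <- function(episodes, id, delta, delta_dot, commit) {
  key <- as.character(id)
  ep <- episodes$active[[key]]
  if (is.null(ep)) {
    dd0 <- delta_dot
    if (commit) episodes$active[[key]] <- list(delta_dot0 = dd0)
    dd0
  } else {
    ep$delta_dot0
  }
}

episodes_keep_active <- function(episodes, ids) {
  keep <- as.character(ids)
  episodes$active <- episodes$active[names(episodes$active) %in% keep]
  invisible(episodes)
}

episodes_end_all <- function(episodes) {
  episodes$active <- list()
  invisible(episodes)
}

# full reset: fresh episodes, logs and warm-start cache
episodes_reset <- function(episodes) {
  episodes$active <- list()
  episodes$log <- list()
  episodes$warm <- NULL
  invisible(episodes)
}

episode_log <- function(episodes, event) {
  episodes$log[[length(episodes$log) + 1L]] <- event
  invisible(episodes)
}
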