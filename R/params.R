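#' Parameter identifiers
#'
#' Sensitivity analyses address model inputs through string ids:
#' `"initial_cost"`, `"cost:<state>"`, `"utility:<state>"`, and
#' `"p:<from>:<to>"` for explicit transition probabilities. Residual
#' transitions have no id of their own: they are recomputed from the
#' explicit mass after any perturbation.
#'
#' @param model A `cea_model`.
#' @return `param_ids()`: character vector of ids addressable in `model`.
#' @export
param_ids <- function(model) {
  c(
    "initial_cost",
    paste0("cost:", model$cost_schedules$state),
    paste0("utility:", setdiff(model$states$name,
                               model$states$name[model$states$absorbing])),
    paste0("p:", model$transitions$from, ":", model$transitions$to)
  )
}

#' @rdname param_ids
#' @param id Parameter id string.
#' @return `param_get()`: the base value(s) — a scalar or per-year vector.
#' @export
param_get <- function(model, id) {
  part <- strsplit(id, ":", fixed = TRUE)[[1]]
  switch(part[1],
    initial_cost = model$initial_one_time_cost,
    cost = {
      i <- match(part[2], model$cost_schedules$state)
      if (is.na(i)) abort(paste0("unknown cost schedule: ", id))
      model$cost_schedules$yearly_costs[[i]]
    },
    utility = {
      i <- match(part[2], model$states$name)
      if (is.na(i)) abort(paste0("unknown state: ", id))
      model$states$utility[i]
    },
    p = {
      i <- which(model$transitions$from == part[2] &
                   model$transitions$to == part[3])
      if (!length(i)) abort(paste0("unknown transition: ", id))
      model$transitions$probability[[i[1]]]
    },
    abort(paste0("unknown parameter id: ", id))
  )
}

#' @rdname param_ids
#' @param values Replacement value(s), same length as the base.
#' @return `param_set()`: the modified model (not re-validated; sensitivity
#'   routines clamp infeasible perturbations instead of erroring).
#' @export
param_set <- function(model, id, values) {
  part <- strsplit(id, ":", fixed = TRUE)[[1]]
  switch(part[1],
    initial_cost = {
      model$initial_one_time_cost <- values
    },
    cost = {
      i <- match(part[2], model$cost_schedules$state)
      model$cost_schedules$yearly_costs[[i]] <- values
    },
    utility = {
      i <- match(part[2], model$states$name)
      model$states$utility[i] <- values
    },
    p = {
      i <- which(model$transitions$from == part[2] &
                   model$transitions$to == part[3])
      model$transitions$probability[[i[1]]] <- values
    },
    abort(paste0("unknown parameter id: ", id))
  )
  model
}
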