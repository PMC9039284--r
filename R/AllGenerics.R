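#' Accessors for acetoflux S4 classes
#'
#' `fluxes()`, `objectiveValue()` and `solverStatus()` extract the pieces of a
#' [FluxSolution-class]; `stoichiometry()`, `reactionIds()`, `bounds()` and
#' `metabolites()` read a [CoreModel-class]; `rates()` and `growthRate()` read
#' a [RatePanel-class]; `carbonFractions()`, `normalisedFractions()` and
#' `recovery()` read a [CarbonBalance-class].
#'
#' @param object the object to access.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
#' @rdname accessors
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setMethod("objectiveValue", "FluxSolution", function(object) object@objectiveValue)

#' @rdname accessors
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))
#' @rdname accessors
#' @export
setMethod("solverStatus", "FluxSolution", function(object) object@status)

#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @rdname accessors
#' @export
setMethod("stoichiometry", "CoreModel", function(object) object@S)

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname accessors
#' @export
setMethod("reactionIds", "CoreModel", function(object) object@reactions$id)

#' @rdname accessors
#' @export
setGeneric("bounds", function(object) standardGeneric("bounds"))
#' @rdname accessors
#' @export
setMethod("bounds", "CoreModel", function(object)
  data.frame(id = object@reactions$id, lb = object@lb, ub = object@ub))

#' @rdname accessors
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))
#' @rdname accessors
#' @export
setMethod("metabolites", "CoreModel", function(object) object@metabolites)

#' @rdname accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))
#' @rdname accessors
#' @export
setMethod("rates", "RatePanel", function(object) object@q)
#' @rdname accessors
#' @export
setMethod("rates", "TruePhysiology", function(object) object@q)

#' @rdname accessors
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))
#' @rdname accessors
#' @export
setMethod("growthRate", "RatePanel", function(object) object@mu)
#' @rdname accessors
#' @export
setMethod("growthRate", "TruePhysiology", function(object) object@mu)

#' @rdname accessors
#' @export
setGeneric("carbonFractions", function(object) standardGeneric("carbonFractions"))
#' @rdname accessors
#' @export
setMethod("carbonFractions", "CarbonBalance", function(object) object@fractions)
#' @rdname accessors
#' @export
setMethod("carbonFractions", "TruePhysiology",
          function(object) object@productCarbonFractions)

#' @rdname accessors
#' @export
setGeneric("normalisedFractions", function(object) standardGeneric("normalisedFractions"))
#' @rdname accessors
#' @export
setMethod("normalisedFractions", "CarbonBalance", function(object) object@normalised)

#' @rdname accessors
#' @export
setGeneric("recovery", function(object) standardGeneric("recovery"))
#' @rdname accessors
#' @export
setMethod("recovery", "CarbonBalance", function(object) object@recovery)

#' @rdname accessors
#' @export
setGeneric("maintenanceATP", function(object) standardGeneric("maintenanceATP"))
#' @rdname accessors
#' @export
setMethod("maintenanceATP", "TruePhysiology", function(object) object@maintenanceATP)
#' @rdname accessors
#' @export
setMethod("maintenanceATP", "FluxSolution",
          function(object) unname(object@fluxes["ATPM"]))
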