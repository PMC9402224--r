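#' Default thalamo-cortical network template
#'
#' The six-region attention network with eight hypothesis-neutral intrinsic
#' connections fixed across the model space, four fronto-thalamic connections
#' permuted over \{absent, present, present-and-modulated\}, and the dPFC->BG
#' connection permuted over \{absent, present-and-modulated\}. The union of
#' fixed and permuted connections is the 13 reported pathways. Driving input
#' enters V1 by default (the sensory entry point of the network), on both
#' condition inputs.
#'
#' @param drivingTargets regions receiving driving input (default "V1").
#' @return A \linkS4class{NetworkTemplate}.
#' @examples
#' tpl <- defaultTemplate()
#' length(tpl@fixed) # 8
#' @export
defaultTemplate <- function(drivingTargets = "V1") {
  new("NetworkTemplate",
      regions = .REGIONS,
      fixed = c("V1->SPC", "V1->Thal", "SPC->Thal", "SPC->BG", "Thal->BG",
                "BG->Thal", "BG->dPFC", "dACC->BG"),
      permuted3 = c("Thal->dPFC", "dPFC->Thal", "Thal->dACC", "dACC->Thal"),
      permuted2 = "dPFC->BG",
      drivingTargets = drivingTargets)
}

#' All pathways of a template
#'
#' @param template a \linkS4class{NetworkTemplate}.
#' @return Character vector of the template's pathways in canonical reporting
#'   order (fixed and permuted combined).
#' @export
templatePathways <- function(template) {
  all <- c(template@fixed, template@permuted3, template@permuted2)
  # report in the canonical table order where applicable
  canon <- .PATHWAYS[.PATHWAYS %in% all]
  c(canon, setdiff(all, canon))
}

#' Permuted pathways of a template
#' @inheritParams templatePathways
#' @return Character vector: the three-state then the two-state connections.
#' @export
permutedPathways <- function(template) {
  c(template@permuted3, template@permuted2)
}

#' Enumerate the model space
#'
#' Cartesian product of the allowed states over the permuted connections, in
#' deterministic lexicographic order: the first permuted connection is the most
#' significant digit and states are ordered ABSENT < PRESENT <
#' PRESENT_MODULATED. The default template yields 3^4 x 2 = 162 models.
#'
#' @param template a \linkS4class{NetworkTemplate}.
#' @return List of \linkS4class{ModelSpec}, model ids 1..K in order.
#' @examples
#' length(enumerateModels(defaultTemplate())) # 162
#' @export
enumerateModels <- function(template) {
  validObject(template)
  conns <- c(template@permuted3, template@permuted2)
  levs <- c(rep(list(.STATES3), length(template@permuted3)),
            rep(list(.STATES2), length(template@permuted2)))
  names(levs) <- conns
  if (length(conns) == 0L) {
    return(list(new("ModelSpec", modelId = 1L,
                    states = setNames(character(), character()))))
  }
  # expand.grid varies the first factor fastest; lexicographic order needs the
  # last listed connection to vary fastest, so expand over the reversed list.
  grid <- expand.grid(rev(levs), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    new("ModelSpec", modelId = i,
        states = setNames(unlist(grid[i, ], use.names = FALSE), conns))
  })
}

#' Binary masks for one model
#'
#' @param spec a \linkS4class{ModelSpec} drawn from the template's space.
#' @param template the \linkS4class{NetworkTemplate}.
#' @return A \linkS4class{MaskSet}: aMask carries the fixed skeleton plus every
#'   permuted connection in state PRESENT or PRESENT_MODULATED; the b masks
#'   carry only PRESENT_MODULATED connections (identically for both demand
#'   conditions); cMask is 1 on the driving-target rows for both inputs.
#' @export
modelMasks <- function(spec, template) {
  validObject(spec); validObject(template)
  conns <- c(template@permuted3, template@permuted2)
  if (!identical(sort(names(spec@states)), sort(conns)))
    stop("model states do not match the template's permuted connections")
  bad2 <- intersect(names(spec@states)[spec@states == "PRESENT"],
                    template@permuted2)
  if (length(bad2))
    stop("two-state connection cannot be PRESENT without modulation: ", bad2)
  n <- length(template@regions)
  a <- matrix(0L, n, n, dimnames = list(template@regions, template@regions))
  b <- a
  a[.connectionIndex(template@fixed, template@regions)] <- 1L
  present <- names(spec@states)[spec@states != "ABSENT"]
  if (length(present))
    a[.connectionIndex(present, template@regions)] <- 1L
  modulated <- names(spec@states)[spec@states == "PRESENT_MODULATED"]
  if (length(modulated))
    b[.connectionIndex(modulated, template@regions)] <- 1L
  cm <- matrix(0L, n, 2L, dimnames = list(template@regions, c("low", "high")))
  cm[match(template@drivingTargets, template@regions), ] <- 1L
  new("MaskSet", aMask = a, bMaskLow = b, bMaskHigh = b, cMask = cm)
}

#' Full parameter names
#'
#' Names of the full parameterization every model embeds into: the 13 intrinsic
#' pathways, the 5 modulable pathways per demand condition, and the driving
#' entries.
#'
#' @inheritParams templatePathways
#' @return Character vector ("A:SRC->DST", "Blow:SRC->DST", "Bhigh:...",
#'   "C:REGION:low"/":high").
#' @export
fullParameterNames <- function(template) {
  perm <- permutedPathways(template)
  c(paste0("A:", templatePathways(template)),
    paste0("Blow:", perm), paste0("Bhigh:", perm),
    paste0("C:", rep(template@drivingTargets, each = 2L), ":",
           c("low", "high")))
}

# Free-parameter index sets for one MaskSet, in canonical flattening order:
# A entries (canonical pathway order), Blow, Bhigh (permuted order), C.
# Returns 0-based (row=target, col=source) index matrices for the C++ layer
# plus parameter names.
.maskIndex <- function(mask, template) {
  regions <- template@regions
  pathA <- templatePathways(template)
  idxA <- .connectionIndex(pathA, regions)
  onA <- mask@aMask[idxA] == 1L
  pathB <- permutedPathways(template)
  idxB <- .connectionIndex(pathB, regions)
  onB <- mask@bMaskLow[idxB] == 1L
  drv <- which(rowSums(mask@cMask) > 0)
  idxC <- cbind(rep(drv, each = 2L), rep(1:2, length(drv)))
  pfx <- function(p, x) if (length(x)) paste0(p, x) else character()
  names <- c(pfx("A:", pathA[onA]),
             pfx("Blow:", pathB[onB]), pfx("Bhigh:", pathB[onB]),
             if (length(drv)) paste0("C:", rep(regions[drv], each = 2L), ":",
                                     c("low", "high")) else character())
  list(iA = idxA[onA, , drop = FALSE] - 1L,
       iB = idxB[onB, , drop = FALSE] - 1L,
       iC = idxC - 1L,
       paramNames = names,
       nA = sum(onA), nB = sum(onB), nC = nrow(idxC))
}

#' Count of free parameters under a mask
#' @param mask a \linkS4class{MaskSet}.
#' @param template the \linkS4class{NetworkTemplate}.
#' @return Integer: free A + B(low) + B(high) + C entries.
#' @export
nFreeParameters <- function(mask, template) {
  ix <- .maskIndex(mask, template)
  ix$nA + 2L * ix$nB + ix$nC
}

#' Serialize a model space to JSON
#'
#' Writes a list of \code{\{model_id, states\}} objects, connections written as
#' "SRC->DST" strings.
#'
#' @param models list of \linkS4class{ModelSpec} (from
#'   \code{\link{enumerateModels}}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeModelSpace <- function(models, path) {
  out <- lapply(models, function(m)
    list(model_id = m@modelId, states = as.list(m@states)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a model space from JSON
#' @param path file written by \code{\link{writeModelSpace}}.
#' @return List of \linkS4class{ModelSpec}.
#' @export
readModelSpace <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(m)
    new("ModelSpec", modelId = as.integer(m$model_id),
        states = unlist(m$states)))
}
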