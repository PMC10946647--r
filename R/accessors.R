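# Accessors and show methods for the package's S4 containers.

#' @name accessors
#' @title Accessors for phyloppc objects
#' @description Small read-only accessors for the package's S4 containers.
#' @param x an object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))
#' @rdname accessors
#' @export
setMethod("nTaxa", "PriorSpec", function(x) x@nTaxa)
#' @rdname accessors
#' @export
setMethod("nTaxa", "Alignment", function(x) nrow(x@seqs))

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setMethod("taxa", "Alignment", function(x) rownames(x@seqs))
#' @rdname accessors
#' @export
setMethod("taxa", "PatternTable", function(x) x@taxa)

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setMethod("nSites", "Alignment", function(x) ncol(x@seqs))
#' @rdname accessors
#' @export
setMethod("nSites", "PatternTable", function(x) sum(x@weights))

#' @rdname accessors
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))
#' @rdname accessors
#' @export
setMethod("alignmentMatrix", "Alignment", function(x) x@seqs)

#' @rdname accessors
#' @export
setGeneric("modelFlavor", function(x) standardGeneric("modelFlavor"))
#' @rdname accessors
#' @export
setMethod("modelFlavor", "PriorSpec", function(x) x@modelFlavor)

#' @rdname accessors
#' @export
setGeneric("baseFreqs", function(x) standardGeneric("baseFreqs"))
#' @rdname accessors
#' @export
setMethod("baseFreqs", "ModelParams", function(x) setNames(x@pi, NUC))

#' @rdname accessors
#' @export
setGeneric("exchangeabilities",
           function(x) standardGeneric("exchangeabilities"))
#' @rdname accessors
#' @export
setMethod("exchangeabilities", "ModelParams",
          function(x) setNames(x@er, ER_NAMES))

#' @rdname accessors
#' @export
setGeneric("gammaShape", function(x) standardGeneric("gammaShape"))
#' @rdname accessors
#' @export
setMethod("gammaShape", "ModelParams", function(x) x@shape)

#' @rdname accessors
#' @export
setGeneric("pInv", function(x) standardGeneric("pInv"))
#' @rdname accessors
#' @export
setMethod("pInv", "ModelParams", function(x) x@pinv)

#' @rdname accessors
#' @export
setGeneric("sampledTrees", function(x) standardGeneric("sampledTrees"))
#' @rdname accessors
#' @export
setMethod("sampledTrees", "PosteriorTrace", function(x) x@trees)

#' @rdname accessors
#' @export
setGeneric("sampledParams", function(x) standardGeneric("sampledParams"))
#' @rdname accessors
#' @export
setMethod("sampledParams", "PosteriorTrace", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("logPosterior", function(x) standardGeneric("logPosterior"))
#' @rdname accessors
#' @export
setMethod("logPosterior", "PosteriorTrace", function(x) x@logPosterior)

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "PosteriorTrace", function(x) length(x@trees))

#' @rdname accessors
#' @export
setGeneric("acceptanceRates", function(x) standardGeneric("acceptanceRates"))
#' @rdname accessors
#' @export
setMethod("acceptanceRates", "PosteriorTrace", function(x) {
  a <- x@acceptance
  a$rate <- ifelse(a$proposed > 0, a$accepted / a$proposed, NA_real_)
  a
})

#' @rdname accessors
#' @export
setGeneric("predictiveSource",
           function(x) standardGeneric("predictiveSource"))
#' @rdname accessors
#' @export
setMethod("predictiveSource", "PredictiveSet", function(x) x@source)

#' @rdname accessors
#' @export
setGeneric("predictiveAlignments",
           function(x) standardGeneric("predictiveAlignments"))
#' @rdname accessors
#' @export
setMethod("predictiveAlignments", "PredictiveSet", function(x) x@alignments)

#' @rdname accessors
#' @export
setGeneric("predictiveThetas",
           function(x) standardGeneric("predictiveThetas"))
#' @rdname accessors
#' @export
setMethod("predictiveThetas", "PredictiveSet",
          function(x) Map(list, tree = x@trees, params = x@params))

setMethod("show", "PriorSpec", function(object) {
  cat("PriorSpec:", object@modelFlavor, "model,", object@nTaxa, "taxa\n")
  cat("  branch lengths ~ Exponential(rate =", object@blRate,
      ") [mean", format(1 / object@blRate), "]\n")
  if (object@modelFlavor == "GTR_GI") {
    cat("  pi ~ Dirichlet(", paste(object@piAlpha, collapse = ", "), ")\n")
    cat("  er ~ Dirichlet(", paste(object@erAlpha, collapse = ", "), ")\n")
    cat("  shape ~ Exponential(rate =", object@shapeRate, ")\n")
    cat("  pinv ~ Beta(", object@pinvBeta[1], ",", object@pinvBeta[2],
        ")\n")
  }
})

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams\n")
  cat("  pi:   ", paste(sprintf("%s=%.4f", NUC, object@pi),
                        collapse = " "), "\n")
  cat("  er:   ", paste(sprintf("%s=%.4f", ER_NAMES, object@er),
                        collapse = " "), "\n")
  cat(sprintf("  shape: %.4f  pinv: %.4f  categories: %d\n", object@shape,
              object@pinv, object@nCategories))
})

setMethod("show", "Alignment", function(object) {
  cat("Alignment:", nrow(object@seqs), "taxa x", ncol(object@seqs),
      "sites\n")
  k <- min(5L, nrow(object@seqs))
  w <- min(60L, ncol(object@seqs))
  for (i in seq_len(k))
    cat(sprintf("  %-12s %s%s\n", rownames(object@seqs)[i],
                paste(object@seqs[i, seq_len(w)], collapse = ""),
                if (ncol(object@seqs) > w) "..." else ""))
  if (nrow(object@seqs) > k) cat("  ...\n")
})

setMethod("show", "PatternTable", function(object) {
  cat("PatternTable:", ncol(object@patterns), "distinct patterns over",
      sum(object@weights), "sites (", length(object@taxa), "taxa )\n")
})

setMethod("show", "MCMCConfig", function(object) {
  cat("MCMCConfig: burn-in", object@burninIters, "/ sampling",
      object@sampleIters, "iterations, thin", object@thin, "\n")
  cat("  tuning every", object@tuneInterval, "iterations",
      if (object@tuneDuringSampling) "(both phases)" else "(burn-in only)",
      "\n")
  w <- object@moveWeights[object@moveWeights > 0]
  cat("  moves:", paste(sprintf("%s=%g", names(w), w), collapse = ", "),
      "\n")
})

setMethod("show", "PosteriorTrace", function(object) {
  cat("PosteriorTrace:", length(object@trees), "samples\n")
  if (length(object@trees)) {
    cat("  log posterior range:",
        paste(format(range(object@logPosterior)), collapse = " .. "), "\n")
    cat("  mean tree length:",
        format(mean(object@params[, "treeLength"])), "\n")
  }
})

setMethod("show", "PredictiveSet", function(object) {
  cat("PredictiveSet (", object@source, " ): ",
      length(object@alignments), " datasets\n", sep = "")
})
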