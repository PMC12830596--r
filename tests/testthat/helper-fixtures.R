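# Shared fixtures, built in code.

smallDesign <- function(...) {
  args <- list(...)
  defaults <- list(nPatients = 2L, biopsiesPerMuscle = 2L,
                   fibresPerSection = 100L, nControlFibres = 300L)
  do.call(CohortDesign, utils::modifyList(defaults, args))
}

# Controls drawn from a known line y = slope * x + intercept + N(0, sd).
makeControls <- function(n = 200, slope = 1.5, intercept = 10, sd = 5,
                         seed = 1, protein = "NDUFB8") {
  set.seed(seed)
  x <- runif(n, 500, 1500)
  out <- data.frame(vdac1 = x)
  out[[protein]] <- slope * x + intercept + rnorm(n, 0, sd)
  out
}

squareAnnotation <- function(investigator = "INV1", protein = "NDUFB8",
                             scope = "S1", category = "low",
                             corners = c(0, 0, 10, 10)) {
  v <- rbind(c(corners[1], corners[2]), c(corners[3], corners[2]),
             c(corners[3], corners[4]), c(corners[1], corners[4]))
  colnames(v) <- c("vdac1", "oxphos")
  list(investigator = investigator, protein = protein, scope = scope,
       category = category, vertices = v)
}

fibreRow <- function(id, x, y, section = "S1", protein = "NDUFB8") {
  out <- data.frame(fibre_id = id, section = section, vdac1 = x)
  out[[protein]] <- y
  out
}
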