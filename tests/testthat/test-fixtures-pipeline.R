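# Fixture libraries, pipeline orchestration, configuration and file I/O.

test_that("the ratio series spans phi in [0, 1] with conserved totals", {
  lib <- generate_ratio_series(n_steps = 8, total_ligands = 38)
  expect_equal(nrow(lib$particles), 8)
  expect_equal(lib$particles$phi, seq(0, 1, length.out = 8))
  counts <- tapply(lib$ligands$count, lib$ligands$particle_id, sum)
  expect_true(all(counts == 38))
  # endpoint particles are monofunctional
  first <- lib$ligands[lib$ligands$particle_id == "ratio_01", ]
  expect_equal(first$count[first$ligand_id == "C12-thiol"], 0)
  last <- lib$ligands[lib$ligands$particle_id == "ratio_08", ]
  expect_equal(last$count[last$ligand_id == "EG2-thiol"], 0)
  expect_error(generate_ratio_series(n_steps = 1),
               class = "vgnp_domain_error")
})

test_that("fixture libraries regenerate and round-trip byte-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_fixture_library(generate_ratio_series(seed = 3), dir1)
  write_fixture_library(generate_ratio_series(seed = 3), dir2)
  for (f in c("particles.csv", "ligands.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  lib2 <- read_particle_library(file.path(dir1, "particles.csv"),
                                file.path(dir1, "ligands.csv"))
  orig <- generate_ratio_series(seed = 3)
  expect_equal(lib2$particles$particle_id, orig$particles$particle_id)
  expect_equal(lib2$ligands$count, orig$ligands$count)
})

test_that("a noiseless synthetic library refits its own generating line", {
  lib <- generate_calibration_library(n = 6, slope = 1.4, intercept = -2,
                                      noise_sd = 0, seed = 1,
                                      core_diameters = 2)
  m <- fit_calibration(lib$particles)
  expect_equal(m$slope, 1.4, tolerance = 1e-9)
  expect_equal(m$intercept, -2, tolerance = 1e-9)
  expect_equal(m$metrics$r_squared, 1)
})

test_that("noise and structure seeds are independent in the library generator", {
  a <- generate_calibration_library(n = 4, slope = 1, intercept = 0,
                                    noise_sd = 0.5, seed = 1,
                                    structure_seed = 9, core_diameters = 2)
  b <- generate_calibration_library(n = 4, slope = 1, intercept = 0,
                                    noise_sd = 0.5, seed = 2,
                                    structure_seed = 9, core_diameters = 2)
  expect_identical(a$particles$log_g_over_r, b$particles$log_g_over_r)
  expect_false(identical(a$particles$elogp, b$particles$elogp))
})

test_that("the pipeline is deterministic and writes regenerable outputs", {
  lib <- generate_ratio_series(n_steps = 3, total_ligands = 10)
  cfg <- vgnp_config(clamp = TRUE)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  r1 <- suppressWarnings(run_pipeline(lib, config = cfg, output_dir = dir1))
  r2 <- suppressWarnings(run_pipeline(lib, config = cfg, output_dir = dir2))
  expect_identical(r1$scores, r2$scores)
  expect_identical(readLines(file.path(dir1, "scores.csv")),
                   readLines(file.path(dir2, "scores.csv")))
  # provenance header carries the full configuration
  hdr <- grep("^#", readLines(file.path(dir1, "scores.csv")), value = TRUE)
  expect_true(any(grepl("config", hdr) & grepl("placement_seed", hdr)))
})

test_that("per-particle failures are recorded and the run continues", {
  particles <- data.frame(particle_id = c("good", "bad"),
                          core_diameter_nm = 2, elogp = NA_real_)
  ligands <- data.frame(particle_id = c("good", "bad"),
                        ligand_id = c("eg2", "broken"),
                        smiles = c("SCCOCCOCCO", "C("), count = c(5, 5))
  expect_warning(
    run <- run_pipeline(particles, ligands, config = vgnp_config()),
    "1 of 2 particles failed")
  expect_true(is.finite(run$scores$log_g_over_r[1]))
  expect_true(is.na(run$scores$log_g_over_r[2]))
  expect_match(run$errors$bad, "broken")
})

test_that("a bare-core library without clamping fails as degenerate", {
  particles <- data.frame(particle_id = "bare", core_diameter_nm = 2)
  ligands <- data.frame(particle_id = character(0), ligand_id = character(0),
                        smiles = character(0), count = numeric(0))
  expect_error(run_pipeline(particles, ligands, config = vgnp_config()),
               class = "vgnp_pipeline_error")
})

test_that("density rows resolve to counts inside the pipeline", {
  particles <- data.frame(particle_id = "dens", core_diameter_nm = 2)
  ligands <- data.frame(particle_id = "dens", ligand_id = "eg2",
                        smiles = "SCCOCCOCCO", density_per_nm2 = 1)
  run <- run_pipeline(particles, ligands, config = vgnp_config(),
                      fit = FALSE)
  # round(4*pi) = 13 copies of a 24-atom ligand
  expect_equal(run$scores$n_atoms, 13 * 24)
})

test_that("configs validate, read from YAML, and honour overrides", {
  cfg <- vgnp_config(h = 0.5, kernel = "audry")
  expect_equal(cfg$h, 0.5)
  expect_error(vgnp_config(h = -1), class = "vgnp_domain_error")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("h: 1.2", "lambda: 2.0", "clamp: true"), path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$h, 1.2)
  expect_true(cfg2$clamp)
  cfg3 <- read_config(path, h = 0.9)
  expect_equal(cfg3$h, 0.9)
  writeLines("banana: 1", path)
  expect_error(read_config(path), class = "vgnp_domain_error")
})

test_that("particle and surface exports are well-formed", {
  p <- build_vgnp(list(ligand_spec("eg2", "SCCOCCOCCO", count = 3)),
                  core_diameter = 2, seed = 1)
  sas <- identify_sas_points(p, h = 1.0)
  surf <- score_surface(sas, p)

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_particle_xyz(p, xyz)
  lines <- readLines(xyz)
  expect_equal(as.integer(lines[1]), nrow(p$atoms))
  expect_equal(length(lines), nrow(p$atoms) + 2)

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_particle_pdb(p, pdb)
  expect_true(any(grepl("^HETATM", readLines(pdb))))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_scored_csv(surf, csv)
  d <- utils::read.csv(csv, comment.char = "#")
  expect_equal(nrow(d), sas$n)
  expect_true(all(d$channel %in% c("G", "R")))
  expect_true(all(d$intensity_normalized >= 0 & d$intensity_normalized <= 1))
  expect_equal(sum(pmax(d$mlp, 0)), surf$i_g, tolerance = 1e-6)
})

test_that("the command-line front end drives the exported functions", {
  cli <- system.file("scripts", "vgnp-cli.R", package = "vgnp")
  out <- system2("Rscript", c(cli, "predict", "--x", "0,1"), stdout = TRUE)
  expect_equal(as.numeric(out), c(-2.4306, -1.6972))

  dir <- withr::local_tempdir()
  system2("Rscript", c(cli, "fixtures", "--type", "ratio", "--out", dir,
                       "--n", "4"), stdout = TRUE)
  lib <- read_particle_library(file.path(dir, "particles.csv"),
                               file.path(dir, "ligands.csv"))
  expect_equal(nrow(lib$particles), 4)
})
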