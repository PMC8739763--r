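# Fixtures built in code: shared tables and configs for the suite.

fixture <- calibration_fixture()

# All event rates zero; transplant rates optionally zero too.
zero_rate_table <- function(tx = 0) {
  b <- fixture$table$brackets
  b$dialysis_mortality <- 0
  b$graft_mortality <- 0
  b$graft_failure_LD <- 0
  b$graft_failure_DD <- 0
  rate_table(b, tx_rate_DD_pediatric = tx, tx_rate_DD_adult = tx,
             tx_rate_third = tx)
}

# Random structurally valid table from the generator.
random_table <- function(seed) generate_rate_tables(generator_spec(seed = seed))

# Uniformly scale one age-stratified field of a table.
scale_field <- function(table, field, factor) {
  table$brackets[[field]] <- table$brackets[[field]] * factor
  table
}

all_sequences <- c("LD-DD", "DD-LD", "DD-DD", "LD-LD")
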