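# Scaled-down run configuration (the full study protocol uses
# population_size: 1000 and generations: 100000).
population_size: 200
generations: 20000
seed: 1
mutation_row_prob: 0.02
mutation_reading_prob: 0.2
mutation_concentration: 0.2
tournament_size: 6
elite_count: 1
fitness_mode: sampled
record_every: 100
block_threshold: 0.8
output_directory: run_out
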