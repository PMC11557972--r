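# Data dictionary

## Observation CSV (canonical long format)

One row per scored (cage, hour) cell. Sleep is scored from the first five
minutes of each hour: a bee counts as asleep when it shows all three sleep
markers — antennal immobility, a non-continuously pulsating abdomen, and leg
immobility — through the 5-minute window; a bee briefly moved by a nestmate
still counts as asleep if it resumes sleep within 30 s.

| column                   | type    | meaning                                                         |
|--------------------------|---------|-----------------------------------------------------------------|
| `cage_id`                | string  | unique cage identifier (e.g. `LL_1`)                            |
| `condition`              | enum    | `LL` constant light, `DD` constant dark, `LD` 12:12 light:dark  |
| `replicate_index`        | integer | 1-based replicate number within the condition                   |
| `hour`                   | integer | hours from experiment onset, 0-based, half-open `[0, duration)` |
| `n_alive`                | count   | bees alive at the scored window (non-increasing in `hour`)      |
| `n_sleeping`             | count   | alive bees asleep in the window; `<= n_alive`                   |
| `n_disturbance_contacts` | count   | contacts received by sleeping bees in the scored 5-min window   |
| `n_sleeping_lower`       | count   | sleepers in the lower 50% of the cage; `<= n_sleeping`          |

Invariants enforced by `read_observations()` / `validate_observations()`:
counts ordered as above, `n_alive` non-increasing per cage, and a complete,
duplicate-free hour grid per cage.

## Light measurement CSV

One row per photon-flux reading taken at the cage top or bottom.

| column        | type   | meaning                                  |
|---------------|--------|------------------------------------------|
| `position`    | enum   | `top` or `bottom` cage section           |
| `photon_flux` | number | photon flux in µmol/m²/s, non-negative   |
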