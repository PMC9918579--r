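# Deposited study archives (not included)

The test suite contains a reproduction check that runs the classifier
and the mixed models over the deposited typed- and spoken-naming study
data (OSF archives `w6ptm` and `gmnc8`). Those archives are third-party
research data and are not redistributed with this package.

To run the reproduction check, download the archives, convert the
Experiment 2 keystroke table to the package's JSON-lines dialect
(see `?read_keylog`), and place the files here as:

    deposited-exp2/events.jsonl        keystroke log (typed naming)
    deposited-exp2/stimuli.csv         names + accepted alternatives
    deposited-exp2/trials.csv          trial table with filler flags
    deposited-exp2/manual_labels.csv   pid, trial, manual_correct
    deposited-exp1/trials.csv          spoken-naming RT table

then reinstall the package and run the tests.
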