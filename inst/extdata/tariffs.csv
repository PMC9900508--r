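item,unit_cost_sek
primary_care_visits,1700
specialist_visits,2600
psychiatric_visits,2400
medication_units,300
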