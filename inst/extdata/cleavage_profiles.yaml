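# Cleavage-profile fixtures for the synthetic tRNA-Leu-TAA reference.
#
# Both base conditions share cut-site coordinates and weights and differ
# only in the methylated fraction m; the protection factor f (= 368/893)
# applies to the protected site 47-64, whose 3' boundary abuts the
# predicted 2'Ome position 65. With site weights 10/6/19 the expected
# share of the 47-64 family among tRFs is
#   (1 - m) * 19/35 + m * (f*19)/(f*19 + 16)
# which evaluates to 50% for af25_low (m = 0.2, snoRNA knocked down)
# and 35% for af25_high (m = 0.9, snoRNA overexpressed).
#
# Stress variants reuse the base parameters and only scale overall
# abundance (hypoxia and oxidative stress raise expression; starvation
# leaves it unchanged).
profiles:
  - name: af25_low
    parent_id: tRNA-Leu-TAA-synthetic-mouse
    methylated_fraction: 0.2
    protection_factor: 0.41209406494960804
    methylation_position: 65
    intact_fraction: 0.3
    end_jitter: 2
    abundance_multiplier: 1.0
    expected_share_47_64: 50.0
    cut_sites:
      - {start: 1, end: 30, weight: 10}
      - {start: 28, end: 45, weight: 6}
      - {start: 47, end: 64, weight: 19}
  - name: af25_high
    parent_id: tRNA-Leu-TAA-synthetic-mouse
    methylated_fraction: 0.9
    protection_factor: 0.41209406494960804
    methylation_position: 65
    intact_fraction: 0.3
    end_jitter: 2
    abundance_multiplier: 1.0
    expected_share_47_64: 35.0
    cut_sites:
      - {start: 1, end: 30, weight: 10}
      - {start: 28, end: 45, weight: 6}
      - {start: 47, end: 64, weight: 19}
  - name: af25_low_hypoxia
    parent_id: tRNA-Leu-TAA-synthetic-mouse
    methylated_fraction: 0.2
    protection_factor: 0.41209406494960804
    methylation_position: 65
    intact_fraction: 0.3
    end_jitter: 2
    abundance_multiplier: 2.0
    cut_sites:
      - {start: 1, end: 30, weight: 10}
      - {start: 28, end: 45, weight: 6}
      - {start: 47, end: 64, weight: 19}
  - name: af25_low_oxidative
    parent_id: tRNA-Leu-TAA-synthetic-mouse
    methylated_fraction: 0.2
    protection_factor: 0.41209406494960804
    methylation_position: 65
    intact_fraction: 0.3
    end_jitter: 2
    abundance_multiplier: 1.6
    cut_sites:
      - {start: 1, end: 30, weight: 10}
      - {start: 28, end: 45, weight: 6}
      - {start: 47, end: 64, weight: 19}
  - name: af25_low_starvation
    parent_id: tRNA-Leu-TAA-synthetic-mouse
    methylated_fraction: 0.2
    protection_factor: 0.41209406494960804
    methylation_position: 65
    intact_fraction: 0.3
    end_jitter: 2
    abundance_multiplier: 1.0
    cut_sites:
      - {start: 1, end: 30, weight: 10}
      - {start: 28, end: 45, weight: 6}
      - {start: 47, end: 64, weight: 19}
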