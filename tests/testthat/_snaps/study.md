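# formatted tables round-trip and snapshot stably

    Code
      cat(lines, sep = "\n")
    Output
      Scenario table1: 5 replicates of 120 subjects
      Mean events 12.2, mean follow-up 583 person-years
      
      alpha (truth 0.200)
      method               mean         SE  coverage(%)
      td_locf            0.2064     0.0342        100.0
      twostage_2y        0.2126     0.0354        100.0
      
      log_lambda (truth -4.828)
      method               mean         SE  coverage(%)
      td_locf           -4.4861     0.4895        100.0
      twostage_2y       -4.3755     0.4689         80.0

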