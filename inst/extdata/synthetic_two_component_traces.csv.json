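{"schema":"ihtrace/traces@1","units":{"t":"ms","V":"mV","I":"pA"},"v_hold":-60,"step_voltages":[-60,-70,-80,-90,-100,-110,-120,-130,-140,-150],"v_post":-60,"t_step":4000,"t_post":1000,"sample_interval":100,"segments":["activation","deactivation"],"noise_sd":10,"seed":20,"Eh":-36,"provenance":"synthetic"}
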