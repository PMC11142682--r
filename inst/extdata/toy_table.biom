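{"id":{},"format":"Biological Observation Matrix 1.0.0","format_url":"http://biom-format.org","type":"OTU table","generated_by":"biomformat 1.30.0","date":"2026-09-22 16:08:34.805271","matrix_type":"dense","matrix_element_type":"int","shape":[4,2],"rows":[{"id":"a","metadata":null},{"id":"b","metadata":null},{"id":"c","metadata":null},{"id":"d","metadata":null}],"columns":[{"id":"s1","metadata":null},{"id":"s2","metadata":null}],"data":[[5.0,2.0],[1.0,2.0],[3.0,4.0],[1.0,2.0]]}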