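a
about
above
after
again
against
all
also
am
among
an
and
any
are
as
at
be
became
because
become
been
before
being
below
between
both
but
by
came
can
cannot
come
could
d
did
do
does
doing
don
down
during
each
even
ever
few
for
from
further
gave
get
give
goes
going
gone
got
had
has
have
having
he
her
here
hers
herself
him
himself
his
how
i
if
in
into
is
it
its
itself
just
let
ll
m
made
me
more
most
my
myself
no
nor
not
now
of
off
on
once
only
or
other
ought
our
ours
ourselves
out
over
own
re
s
said
same
say
shan
she
should
since
so
some
such
t
than
that
the
their
theirs
them
themselves
then
there
these
they
this
those
through
to
too
under
until
up
upon
ve
very
was
we
went
were
what
when
where
which
while
who
whom
why
will
with
won
would
you
your
yours
yourself
yourselves
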